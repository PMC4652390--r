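test_that("read trimming removes the 5' prefix and locates the adapter", {
  prefix <- "CAGTACGT"
  adapter <- "AGATCGGAAGAGC"
  set.seed(1)
  insert <- rand_dna(25)
  reads <- c(r1 = paste0(prefix, insert, substr(adapter, 1, 3)),
             r2 = paste0(prefix, rand_dna(11), substr(adapter, 1, 17 + 8)))
  tags <- trim_reads(reads, adapter, nchar(prefix), min_len = 20L)
  # r1 keeps its 25-bp insert; r2 trims to 11 bp and is dropped
  expect_equal(tags$read_id, "r1")
  expect_equal(tags$seq, insert)
  expect_equal(attr(tags, "retention"), 0.5)
  expect_warning(empty <- trim_reads(character(0), adapter, 8L), "no reads")
  expect_equal(nrow(empty), 0L)
})

test_that("trimming survives a single adapter mismatch per 10 bases", {
  adapter <- "AGATCGGAAGAGC"
  insert <- strrep("C", 22)
  ad <- adapter
  substr(ad, 5, 5) <- "T" # 1 mismatch in a 13-bp overlap: allowed
  read <- c(r = paste0(insert, ad))
  tags <- trim_reads(read, adapter, 0L, min_len = 20L)
  expect_equal(tags$seq, insert)
})

test_that("FASTQ reads round-trip through file and trimming", {
  cfg <- small_sim_config(seed = 3, n_genes = 15, cage_depth = 200,
                          cage_unalignable = 0, promoter_divergence = 0,
                          indel_rate = 0, repeat_prob = 0,
                          duplication_fraction = 0)
  sim <- simulate_genome_pair(cfg)
  reads <- simulate_cage_fastq(sim)
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  tags <- trim_reads(fq, cfg$adapter_3p, nchar(cfg$prefix_5p))
  expect_equal(attr(tags, "retention"), 1)
  expect_true(all(nchar(tags$seq) == 25L))
  # at zero divergence every planted insert is target-genome sequence
  g <- as.character(sim$target_genome$seqs[["chr1"]])
  rcg <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g)))
  hitg <- vapply(tags$seq[1:50], function(s)
    grepl(s, g, fixed = TRUE) || grepl(s, rcg, fixed = TRUE), logical(1))
  expect_true(all(hitg))
})

test_that("tag resolution applies the 0.95 ratio and scaffold clauses", {
  set.seed(41)
  core <- rand_dna(25)
  near <- core
  substr(near, 12, 12) <- flip_base(substr(near, 12, 12))
  # chr copy + scaffold identical copy -> scaffold clause resolves to chr
  gen1 <- genome_sequence(
    c(chr1 = paste0(rand_dna(3000), core, rand_dna(3000)),
      GL0001 = paste0(rand_dna(500), core, rand_dna(500))))
  t1 <- align_cage_tags(data.frame(read_id = "t", seq = core,
                                   stringsAsFactors = FALSE), gen1)
  expect_equal(t1$map_class, "unique")
  expect_equal(t1$contig, "chr1")
  expect_equal(t1$n_hits, 2L)
  # two identical chromosome copies -> multimapped
  gen2 <- genome_sequence(
    c(chr1 = paste0(rand_dna(3000), core, rand_dna(3000), core,
                    rand_dna(500))))
  t2 <- align_cage_tags(data.frame(read_id = "t", seq = core,
                                   stringsAsFactors = FALSE), gen2)
  expect_equal(t2$map_class, "multimapped")
  # exact copy beats a 1-mismatch copy through the score ratio
  gen3 <- genome_sequence(
    c(chr1 = paste0(rand_dna(3000), core, rand_dna(3000), near,
                    rand_dna(500))))
  t3 <- align_cage_tags(data.frame(read_id = "t", seq = core,
                                   stringsAsFactors = FALSE), gen3)
  expect_equal(t3$map_class, "unique")
  expect_equal(t3$start, 3001L)
})

test_that("iterative trimming rescues end-corrupted tags and respects the floor", {
  set.seed(52)
  g <- rand_dna(40000)
  gen <- genome_sequence(c(chr1 = g))
  idx <- genome_index(gen)
  core <- substr(g, 10001, 10022) # 22 bp of true sequence
  bad3 <- vapply(substr(g, 9998, 10000) |> strsplit("") |> unlist(),
                 flip_base, character(1))
  tag <- paste0(paste(bad3, collapse = ""), core) # needs clip 3: unmapped
  tags <- align_cage_tags(data.frame(read_id = "t", seq = tag,
                                     stringsAsFactors = FALSE),
                          index = idx)
  expect_equal(tags$map_class, "unmapped")
  rescued <- iterative_trim_rescue(tags, index = idx)
  expect_equal(rescued$map_class, "rescued")
  expect_equal(rescued$trim_iterations, 1L)
  expect_equal(rescued$start, 10001L)
  # a 12-bp unmapped tag would fall below 11 bp: never realigned
  t12 <- align_cage_tags(data.frame(read_id = "s", seq = rand_dna(12),
                                    stringsAsFactors = FALSE),
                         index = idx)
  r12 <- iterative_trim_rescue(t12, index = idx)
  expect_equal(r12$map_class, "unmapped")
  expect_equal(r12$trim_iterations, 0L)
  # rescue never converts a mapped tag
  mapped <- align_cage_tags(data.frame(read_id = "m",
                                       seq = substr(g, 501, 525),
                                       stringsAsFactors = FALSE),
                            index = idx)
  expect_equal(iterative_trim_rescue(mapped, index = idx)$map_class,
               "unique")
})

test_that("extension to promoter length splits the padding 5'-heavy", {
  # 25-bp placement at BED (1000, 1025): 238 added each side
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1025),
                               strand = "+")
  e <- extend_to_promoter_length(gr)
  expect_equal(GenomicRanges::start(e), 763L)
  expect_equal(GenomicRanges::end(e), 1263L)
  expect_equal(GenomicRanges::width(e), 501L)
  # 24-bp placement: 239 five-prime / 238 three-prime
  gr24p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1024),
                                  strand = "+")
  e24 <- extend_to_promoter_length(gr24p)
  expect_equal(GenomicRanges::start(e24), 1001L - 239L)
  expect_equal(GenomicRanges::end(e24), 1024L + 238L)
  gr24m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1024),
                                  strand = "-")
  e24m <- extend_to_promoter_length(gr24m)
  expect_equal(GenomicRanges::start(e24m), 1001L - 238L)
  expect_equal(GenomicRanges::end(e24m), 1024L + 239L)
  # clipping at the contig start; longer placements left unchanged
  genome <- genome_sequence(c(chr1 = strrep("A", 5000)))
  near0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 75),
                                  strand = "+")
  en <- extend_to_promoter_length(near0, genome = genome)
  expect_equal(GenomicRanges::start(en), 1L)
  long <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 600),
                                 strand = "+")
  expect_warning(el <- extend_to_promoter_length(long), "unchanged")
  expect_equal(GenomicRanges::width(el), 600L)
})

test_that("CTSS clustering merges overlap but not abutment, per strand", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 501), c(601, 1001)),
                               strand = "+")
  cl <- cluster_ctss(gr)
  expect_length(cl, 1L)
  expect_equal(GenomicRanges::start(cl), 101L)
  expect_equal(GenomicRanges::end(cl), 1001L)
  expect_equal(cl$tag_count, 2L)
  # abutting intervals (BED (100,601) and (601,1102)) stay separate
  ab <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 602), c(601, 1102)),
                               strand = "+")
  expect_length(cluster_ctss(ab), 2L)
  # identical intervals on opposite strands form two clusters
  tw <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101, 101), c(601, 601)),
                               strand = c("+", "-"))
  expect_length(cluster_ctss(tw), 2L)
  # idempotence and singleton removal
  again <- cluster_ctss(GenomicRanges::granges(cl))
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(cl))
  expect_length(drop_singletons(cluster_ctss(tw)), 0L)
})

test_that("clustering matches the all-pairs merge oracle", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    st <- sample(1:20000, n, replace = TRUE)
    gr <- GenomicRanges::GRanges("c1",
                                 IRanges::IRanges(st, st + sample(50:501, n,
                                                                  TRUE)),
                                 strand = "+")
    got <- cluster_ctss(gr)
    want <- cluster_oracle(GenomicRanges::start(gr),
                           GenomicRanges::end(gr))
    want <- want[order(want[, "start"]), , drop = FALSE]
    expect_equal(GenomicRanges::start(got), unname(want[, "start"]))
    expect_equal(GenomicRanges::end(got), unname(want[, "end"]))
    expect_equal(got$tag_count, unname(as.integer(want[, "n"])))
    # tag counts add up to the number of placements
    expect_equal(sum(got$tag_count), n)
  }
})

test_that("clusters assign to overlapping or 2-kb-upstream genes", {
  genes <- gene_models(c("g1", "g2"), "chr1", c(10000, 20000),
                       c(12000, 22000), c("+", "-"))
  cl <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(9001, 11000, 6800, 22500),
                                                c(9400, 11400, 6950, 22900)),
                               strand = "+")
  got <- cluster_gene_assignment(cl, genes)
  # 1 kb upstream of g1; inside g1; 3 kb upstream (unassigned);
  # 500 bp upstream of minus-strand g2
  expect_equal(got, c("g1", "g1", NA, "g2"))
})

test_that("proximity fractions honour both distance cutoffs", {
  clusters <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(1000, 5000),
                                                      c(1400, 5400)))
  prom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, 1700))
  px <- promoter_ctss_proximity(clusters, prom, d = c(100, 2000))
  # cluster 1 overlaps; cluster 2 sits 3.3 kb away
  expect_equal(px$cluster_to_promoter, c(0.5, 0.5))
  expect_equal(px$promoter_to_cluster, c(1, 1))
  gap150 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1851, 2100))
  px2 <- promoter_ctss_proximity(gap150, prom, d = c(100, 2000))
  expect_equal(px2$cluster_to_promoter, c(0, 1))
})

test_that("the tag ledger is conserved through the pipeline", {
  cfg <- small_sim_config(seed = 9, n_genes = 25, cage_depth = 1500,
                          duplication_fraction = 0.1)
  sim <- simulate_genome_pair(cfg)
  reads <- simulate_cage_fastq(sim)
  out <- cage_pipeline(reads, sim$target_genome,
                       adapter_3p = cfg$adapter_3p,
                       prefix_5p_len = nchar(cfg$prefix_5p))
  s <- out$stats
  expect_equal(unname(s["n_unique"] + s["n_rescued"] +
                        s["n_multimapped"] + s["n_unmapped"]),
               unname(s["n_reads_kept"]))
  expect_equal(sum(out$clusters$tag_count), length(out$placements))
  expect_equal(unname(s["n_clusters_supported"]),
               unname(s["n_clusters"] - s["n_singletons"]))
  # all extended placements are promoter-length away from contig edges
  expect_true(all(GenomicRanges::width(out$extended) <= 501L))
})
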