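test_that("promoter windows span [-400, +100] around the TSS", {
  genome <- genome_sequence(c(chr1 = strrep("A", 10000)))
  w <- build_promoter_window(c(1001L, 1001L, 201L), c("+", "-", "+"),
                             rep("chr1", 3), genome)
  # BED terms: (600, 1101), (900, 1401), (0, 301)
  expect_equal(w$start, c(601L, 901L, 1L))
  expect_equal(w$end, c(1101L, 1401L, 301L))
  expect_equal(w$edge_truncated, c(FALSE, FALSE, TRUE))
  expect_equal(w$excluded, c(FALSE, FALSE, FALSE))
  # clipping below 250 bp excludes the promoter from projection
  w2 <- build_promoter_window(100L, "+", "chr1", genome)
  expect_true(w2$excluded)
})

test_that("ortholog windows span 2 kb upstream plus 101 bases", {
  genome <- genome_sequence(c(chr1 = strrep("A", 20000)))
  genes <- gene_models(c("g1", "g2", "g3"), "chr1",
                       c(5001, 3001, 1001), c(5400, 5001, 1400),
                       c("+", "-", "+"))
  w <- build_ortholog_window(genes, genome)
  expect_equal(GenomicRanges::start(w), c(3001L, 4901L, 1L))
  expect_equal(GenomicRanges::end(w), c(5101L, 7001L, 1101L))
  expect_equal(w$truncated, c(FALSE, FALSE, TRUE))
})

test_that("promoter classes follow the gene/ortholog association", {
  genome <- genome_sequence(c(chr1 = strrep("A", 10000)))
  p <- promoter_set(c("a", "b", "c"), "chr1", c(2000, 3000, 4000), "+",
                    gene_id = c("g1", "g2", NA),
                    has_target_ortholog = c(TRUE, FALSE, FALSE),
                    genome = genome)
  expect_equal(p$anno_class, c("c11", "c10", "c00"))
  expect_error(promoter_set(c("a", "a"), "chr1", c(1, 2), "+"),
               "duplicate")
})

test_that("multimapper rescue applies the ratio then the scaffold clause", {
  cls <- c(chr1 = "chromosome", chr2 = "chromosome",
           GL0001 = "unplaced_scaffold")
  mk <- function(bits, contigs)
    data.frame(contig = contigs, start = seq_along(bits) * 1000L,
               end = seq_along(bits) * 1000L + 500L, strand = "+",
               raw_score = bits, bit_score = bits,
               stringsAsFactors = FALSE)
  r <- rescue_multimapped(mk(c(100, 90), c("chr1", "chr2")), cls)
  expect_equal(r$status, "rescued_ratio")
  expect_equal(r$hit$bit_score, 100)
  r <- rescue_multimapped(mk(c(100, 98), c("chr1", "GL0001")), cls)
  expect_equal(r$status, "rescued_scaffold")
  expect_equal(r$hit$contig, "chr1")
  r <- rescue_multimapped(mk(c(100, 98), c("chr1", "chr2")), cls)
  expect_equal(r$status, "multimapped")
  expect_null(r$hit)
  # the scaffold clause can be limited to the literal two-hit case
  r <- rescue_multimapped(mk(c(100, 98, 97), c("chr1", "GL0001", "GL0001")),
                          cls, scaffold_max_hits = 2)
  expect_equal(r$status, "multimapped")
  r <- rescue_multimapped(mk(c(100, 98, 97), c("chr1", "GL0001", "GL0001")),
                          cls)
  expect_equal(r$status, "rescued_scaffold")
})

test_that("raising the ratio threshold never loses rescued promoters", {
  set.seed(19)
  cls <- c(chr1 = "chromosome", chr2 = "chromosome")
  n_rescued <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(ratio) {
    cnt <- 0L
    set.seed(19)
    for (i in 1:200) {
      bits <- sort(runif(2, 50, 100), decreasing = TRUE)
      h <- data.frame(contig = c("chr1", "chr2"), start = c(1L, 2L),
                      end = c(501L, 502L), strand = "+",
                      raw_score = bits, bit_score = bits)
      if (rescue_multimapped(h, cls, ratio = ratio)$status ==
          "rescued_ratio") cnt <- cnt + 1L
    }
    cnt
  }, integer(1))
  expect_true(all(diff(n_rescued) >= 0L))
})

test_that("projection at zero divergence is exact and deterministic", {
  cfg <- small_sim_config(seed = 4, n_genes = 25,
                          promoter_divergence = 0, indel_rate = 0,
                          repeat_prob = 0, duplication_fraction = 0)
  sim <- simulate_genome_pair(cfg)
  res <- project_promoters(sim$promoters, sim$source_genome,
                           sim$target_genome, sim$orthologs,
                           sim$target_genes)
  expect_true(all(is_reported(res)))
  expect_equal(res$start, sim$truth$t_start)
  expect_equal(res$end, sim$truth$t_end)
  res2 <- project_promoters(sim$promoters, sim$source_genome,
                            sim$target_genome, sim$orthologs,
                            sim$target_genes)
  expect_identical(res, res2)
})

test_that("statuses partition the promoter set", {
  cfg <- small_sim_config(seed = 6, n_genes = 30,
                          duplication_fraction = 0.1)
  sim <- simulate_genome_pair(cfg)
  res <- project_promoters(sim$promoters, sim$source_genome,
                           sim$target_genome, sim$orthologs,
                           sim$target_genes)
  expect_equal(nrow(res), nrow(sim$promoters))
  expect_equal(anyDuplicated(res$promoter_id), 0L)
  valid <- c("ortholog_mapped", "unique", "rescued_ratio",
             "rescued_scaffold", "multimapped", "unmapped")
  expect_true(all(res$status %in% valid))
  expect_equal(sum(is_reported(res)) + sum(!is_reported(res)), nrow(res))
  # chosen placement present exactly for reported promoters
  expect_equal(!is.na(res$start), is_reported(res))
})

test_that("c00 promoters pass through the orthology stage untouched", {
  cfg <- small_sim_config(seed = 14, n_genes = 20,
                          gene_assoc_fraction = 0)
  sim <- simulate_genome_pair(cfg)
  om <- map_via_orthology(sim$promoters,
                          source_genome = sim$source_genome,
                          target_genome = sim$target_genome,
                          orthologs = sim$orthologs,
                          target_genes = sim$target_genes)
  expect_equal(nrow(om$results), 0L)
  expect_setequal(om$pass_through, sim$promoters$promoter_id)
})

test_that("with two target orthologs the best bit-score wins", {
  set.seed(23)
  core <- rand_dna(501)
  # ortholog A carries the exact homolog, B a diverged copy
  mutated <- strsplit(core, "")[[1]]
  pos <- sample(501, 60)
  mutated[pos] <- flip_base(mutated[pos])
  gA <- paste0(rand_dna(1700), core, rand_dna(300))
  gB <- paste0(rand_dna(1700), paste(mutated, collapse = ""),
               rand_dna(300))
  tg <- genome_sequence(c(chrA = gA, chrB = gB))
  genes <- gene_models(c("tA", "tB"), c("chrA", "chrB"),
                       c(2201, 2201), c(2500, 2500), "+")
  src <- genome_sequence(c(s1 = paste0(rand_dna(500), core,
                                       rand_dna(500))))
  prom <- promoter_set("p1", "s1", 901L, "+", gene_id = "g1",
                       has_target_ortholog = TRUE, genome = src)
  orth <- ortholog_table(c("g1", "g1"), c("tA", "tB"))
  om <- map_via_orthology(prom, source_genome = src, target_genome = tg,
                          orthologs = orth, target_genes = genes)
  expect_equal(om$results$status, "ortholog_mapped")
  expect_equal(om$results$contig, "chrA")
  expect_equal(om$results$start, 1701L)
})

test_that("20-kb upstream check is strand-aware and contig-bound", {
  genes <- gene_models(c("g1", "g1", "g1"), "chr1",
                       rep(50000, 3), rep(50400, 3), "+")
  res <- data.frame(promoter_id = c("a", "b", "c"),
                    status = rep("unique", 3),
                    contig = c("chr1", "chr1", "chr2"),
                    start = c(45001, 24001, 45001),
                    end = c(45501, 24501, 45501),
                    strand = "+", raw_score = 1, bit_score = 1,
                    n_hits = 1L, midpoint = 1L,
                    stringsAsFactors = FALSE)
  expect_equal(within_upstream_of_ortholog(res, genes),
               c(TRUE, FALSE, FALSE))
  # minus-strand gene: upstream lies to the right
  genes_m <- gene_models("g2", "chr1", 10000, 10400, "-")
  res_m <- res[1, ]; res_m$start <- 15001; res_m$end <- 15501
  expect_true(within_upstream_of_ortholog(res_m, genes_m))
})
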