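test_that("FPKM follows the closed form and discards ambiguous fragments", {
  genes <- gene_models(c("g1", "g2"), "chr1", c(1000, 5000),
                       c(1999, 5999), "+")
  # 10 unique fragments in g1, one multimapped, one overlapping both
  frags <- aligned_fragments("chr1",
                             c(seq(1100, 1900, length.out = 10), 1200,
                               1950),
                             c(seq(1100, 1900, length.out = 10) + 99, 1299,
                               5049),
                             multimapped = c(rep(FALSE, 10), TRUE, FALSE))
  out <- gene_counts_fpkm(frags, genes, library_size = 1e6)
  expect_equal(out$count, c(10L, 0L))
  expect_equal(out$fpkm[1], 10 * 1e9 / (1000 * 1e6)) # = 10
  expect_equal(out$fpkm[2], 0)
  expect_error(gene_counts_fpkm(frags, genes, 0), "positive")
  # FPKM scales linearly with count and inversely with library size
  out2 <- gene_counts_fpkm(frags, genes, library_size = 2e6)
  expect_equal(out2$fpkm[1], out$fpkm[1] / 2)
  expect_lte(sum(out$count), length(frags))
})

test_that("planted 3:1 expression is recovered within binomial bounds", {
  cfg <- small_sim_config(seed = 17, n_genes = 20, rnaseq_depth = 20000,
                          duplication_fraction = 0)
  sim <- simulate_genome_pair(cfg)
  sim$truth$expr <- c(3, 1, rep(0, 18))
  rna <- simulate_rnaseq_fragments(sim)
  out <- gene_counts_fpkm(rna$fragments, sim$target_genes,
                          rna$library_size)
  expect_true(all(out$count[-(1:2)] == 0L))
  expect_true(all(out$fpkm[-(1:2)] == 0))
  n <- out$count[1] + out$count[2]
  # equal exonic lengths: expected share 0.75 with exact binomial bounds
  bounds <- stats::qbinom(c(5e-4, 1 - 5e-4), n, 0.75)
  expect_gte(out$count[1], bounds[1])
  expect_lte(out$count[1], bounds[2])
  expect_equal(out$fpkm[1] / out$fpkm[2], out$count[1] / out$count[2])
})

mk_mapped <- function(contig, midpoint, strand, id = "p1")
  data.frame(promoter_id = id, status = "unique", contig = contig,
             start = midpoint - 250L, end = midpoint + 250L,
             strand = strand, raw_score = 1, bit_score = 1, n_hits = 1L,
             midpoint = midpoint, stringsAsFactors = FALSE)

test_that("window coverage bins fragments 5' to 3' around the midpoint", {
  res <- mk_mapped("chr1", 100000L, "+")
  # fragment fully inside the midpoint window
  f1 <- aligned_fragments("chr1", 100010, 100060)
  mat <- window_coverage(res, f1)
  expect_equal(dim(mat), c(1L, 250L))
  expect_equal(attr(mat, "midpoint_window"), 51L)
  expect_equal(which(mat[1, ] > 0), 51L)
  # a 150-bp fragment straddling two windows increments both
  f2 <- aligned_fragments("chr1", 100050, 100199)
  mat2 <- window_coverage(res, f2)
  expect_equal(which(mat2[1, ] > 0), c(51L, 52L))
  # minus strand: columns mirror so column 1 is 5'-most; brute-force
  # expectation: post-reversal window j covers genomic
  # [mid + 5000 - j*100 + 1, mid + 5000 - (j-1)*100]
  resm <- mk_mapped("chr1", 100000L, "-")
  f3 <- aligned_fragments("chr1", 100290, 100310) # 300 bp 5' of midpoint
  mat3 <- window_coverage(resm, f3)
  mid <- 100000
  want <- which(vapply(1:250, function(j) {
    ws <- mid + 5000 - j * 100 + 1; we <- mid + 5000 - (j - 1) * 100
    100290 <= we && 100310 >= ws
  }, logical(1)))
  expect_equal(which(mat3[1, ] > 0), want)
  # the midpoint base itself falls in column 51 on either strand
  point <- aligned_fragments("chr1", 100000, 100000)
  expect_equal(which(window_coverage(res, point)[1, ] > 0), 51L)
  expect_equal(which(window_coverage(resm, point)[1, ] > 0), 51L)
})

test_that("strand flip leaves the oriented coverage matrix invariant", {
  glen <- 300000L
  set.seed(71)
  fs <- sample(60000:240000, 400)
  res <- mk_mapped("chr1", 150000L, "+")
  mat_p <- window_coverage(res, aligned_fragments("chr1", fs, fs + 120L))
  # mirror the genome: position x -> glen - x + 1
  res_m <- mk_mapped("chr1", glen - 150000L + 1L, "-")
  mfs <- glen - (fs + 120L) + 1L
  mat_m <- window_coverage(res_m, aligned_fragments("chr1", mfs,
                                                    mfs + 120L))
  expect_equal(unname(mat_p), unname(mat_m))
})

test_that("heatmap filter keeps rows with >= 11 reads in the first 100 windows", {
  mat <- matrix(0L, nrow = 3, ncol = 250,
                dimnames = list(c("a", "b", "c"), NULL))
  mat[1, 1:11] <- 1L   # 11 reads: kept
  mat[2, 1:10] <- 1L   # 10 reads: dropped
  mat[3, 150] <- 100L  # distal only: dropped
  attr(mat, "midpoint_window") <- 51L
  attr(mat, "contig") <- c("chr1", "chr1", "chr2")
  out <- heatmap_subset(mat)
  expect_equal(rownames(out), "a")
  expect_equal(attr(out, "contig"), "chr1")
  empty <- heatmap_subset(matrix(0L, 2, 250,
                                 dimnames = list(c("x", "y"), NULL)))
  expect_equal(nrow(empty), 0L)
})

test_that("the evidence call inspects exactly the seven midpoint windows", {
  mk <- function(cols, counts = 1L) {
    m <- matrix(0L, 1, 250, dimnames = list("p", NULL))
    m[1, cols] <- counts
    attr(m, "midpoint_window") <- 51L
    m
  }
  lib <- 1e6
  # count 1 in a window: FPKM = 1e9 / (100 * 1e6) = 10 >= 1
  expect_true(rnaseq_evidence_call(mk(51), lib))
  expect_true(rnaseq_evidence_call(mk(49), lib))  # m - 2
  expect_true(rnaseq_evidence_call(mk(55), lib))  # m + 4
  expect_false(rnaseq_evidence_call(mk(48), lib)) # outside 5' edge
  expect_false(rnaseq_evidence_call(mk(56), lib)) # m + 5: outside
  expect_false(rnaseq_evidence_call(mk(150, 1000L), lib)) # distal only
  # sub-threshold FPKM across all seven windows
  expect_false(rnaseq_evidence_call(mk(51), 2e10))
})

test_that("evidence integration categorises CAGE x RNA-Seq support", {
  prom <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1000, 50000, 90000,
                                                    130000),
                                                  c(1500, 50500, 90500,
                                                    130500)))
  prom$promoter_id <- paste0("p", 1:4)
  clusters <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(1600, 91000),
                                                      c(1900, 91200)))
  clusters$tag_count <- c(5L, 2L)
  rna <- c(p1 = TRUE, p2 = TRUE, p3 = FALSE, p4 = FALSE)
  out <- integrate_evidence(prom, clusters, NULL, rna)
  expect_equal(out$calls$category,
               c("both", "rnaseq_only", "cage_only", "none"))
  expect_equal(unname(out$summary["frac_supported"]), 0.75)
  expect_equal(unname(out$summary["frac_both"]), 0.25)
  # uniquely mapped singleton tags extend the CAGE feature set
  singles <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(131000, 131400))
  out2 <- integrate_evidence(prom, clusters, singles, rna)
  expect_equal(out2$calls$category[4], "cage_only")
})
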