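# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

flip_base <- function(b) unname(c(A = "C", C = "G", G = "T", T = "A")[b])

small_layout <- function(chr_len = 70000L, scaf_len = 10000L)
  data.frame(name = c("chr1", "scaffold_1"),
             length = c(chr_len, scaf_len),
             class = c("chromosome", "unplaced_scaffold"),
             stringsAsFactors = FALSE)

small_sim_config <- function(seed = 11L, n_genes = 60L, ...)
  sim_config(seed = seed, n_genes = n_genes,
             contig_layout = small_layout(), ...)

random_genome <- function(len = 50000L, seed = 1L) {
  set.seed(seed)
  genome_sequence(setNames(rand_dna(len), "chr1"))
}

# Independent O(n) nearest-feature scan (gap semantics, leftmost ties).
closest_scan <- function(q_start, q_end, f_start, f_end, max_dist) {
  best <- NA_integer_; bdist <- NA_integer_
  for (j in seq_along(f_start)) {
    gap <- max(0L, max(f_start[j] - q_end - 1L, q_start - f_end[j] - 1L))
    if (gap > max_dist) next
    if (is.na(bdist) || gap < bdist ||
        (gap == bdist && f_start[j] < f_start[best])) {
      best <- j; bdist <- gap
    }
  }
  list(idx = best, dist = bdist)
}

# Independent O(n^2) single-linkage merge of intervals overlapping by >=1
# base (abutting intervals stay separate).
cluster_oracle <- function(start, end) {
  n <- length(start)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && start[i] <= end[j] && start[j] <= end[i]) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  t(vapply(unique(comp), function(cc) {
    m <- comp == cc
    c(start = min(start[m]), end = max(end[m]), n = sum(m))
  }, numeric(3)))
}

# Truth-recovery helpers
midpoint_ok <- function(results, truth, tol = 10) {
  !is.na(results$start) &
    abs((results$start + results$end) / 2 -
          (truth$t_start + truth$t_end) / 2) <= tol
}
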