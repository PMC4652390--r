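#' Local-alignment scoring scheme
#'
#' Parameters of the seeded local aligner plus the Karlin-Altschul
#' constants used to convert raw scores to bit-scores and e-values:
#' `bit = (lambda * S - ln K) / ln 2` and
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the total unmasked genome length. Gap cost of a length-k gap is
#' `gap_open + k * gap_extend` (so `gap_open = 0` means opening is free).
#'
#' @param reward match reward (> 0).
#' @param penalty mismatch score (<= 0).
#' @param gap_open,gap_extend gap parameters (see above).
#' @param min_identity minimum percent identity for a reported hit.
#' @param max_evalue e-value cutoff.
#' @param lambda,K Karlin-Altschul constants for this reward/penalty pair.
#' @return object of class `ScoringScheme`.
#' @export
scoring_scheme <- function(reward = 1L, penalty = -1L, gap_open = 0L,
                           gap_extend = 2L, min_identity = 20,
                           max_evalue = 0.01, lambda = 1.28, K = 0.46) {
  stopifnot(reward > 0, penalty <= 0, lambda > 0, K > 0)
  structure(list(reward = as.integer(reward), penalty = as.integer(penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity, max_evalue = max_evalue,
                 lambda = lambda, K = K),
            class = "ScoringScheme")
}

#' First-pass scheme: tolerant scoring for diverged promoter windows
#' (reward 1, penalty -1, gap open 0, gap extend 2, identity >= 20%,
#' e-value <= 0.01).
#' @rdname scoring_scheme
#' @export
scheme_pass1 <- function() scoring_scheme(1L, -1L, 0L, 2L, 20, 0.01,
                                          lambda = 1.28, K = 0.46)

#' Second-pass scheme for promoters unmapped after pass 1: stricter
#' mismatch scoring (reward 1, penalty -3, gap open 3, gap extend 3);
#' identity and e-value cutoffs carried over from pass 1.
#' @rdname scoring_scheme
#' @export
scheme_pass2 <- function() scoring_scheme(1L, -3L, 3L, 3L, 20, 0.01,
                                          lambda = 1.37, K = 0.71)

#' Short-tag scheme used for CAGE tag alignment (strict mismatch scoring
#' against the unmasked genome; identity floor raised since tags are
#' same-species sequence).
#' @rdname scoring_scheme
#' @export
scheme_tags <- function() scoring_scheme(1L, -3L, 3L, 3L, 80, 0.001,
                                         lambda = 1.37, K = 0.71)

#' Raw score to bit-score conversion
#' @param raw_score integer raw alignment score(s).
#' @param scheme `ScoringScheme`.
#' @export
bit_score <- function(raw_score, scheme)
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)

evalue_of <- function(raw_score, scheme, m, n)
  scheme$K * m * n * exp(-scheme$lambda * raw_score)

# Smallest raw score that can pass the e-value cutoff; used to prune the
# search in C++ before statistics are computed.
min_raw_for_evalue <- function(scheme, m, n) {
  s <- ceiling((log(scheme$K * m * max(n, 1)) -
                  log(scheme$max_evalue)) / scheme$lambda)
  max(1L, as.integer(s))
}

#' Build a reusable k-mer index over a genome
#'
#' @param genome `GenomeSequence`.
#' @param k seed length (default 11, the pipeline's global minimum query
#'   length).
#' @return object of class `GenomeIndex` wrapping an external pointer;
#'   rebuild rather than serialize.
#' @export
genome_index <- function(genome, k = 11L) {
  masks <- lapply(names(genome$seqs), function(cn) {
    m <- genome$mask[GenomicRanges::seqnames(genome$mask) == cn]
    if (!length(m)) return(NULL)
    cbind(GenomicRanges::start(m), GenomicRanges::end(m))
  })
  ptr <- cpp_index_build(names(genome$seqs),
                         as.character(genome$seqs), masks, as.integer(k))
  unmasked <- sum(Biostrings::width(genome$seqs)) -
    sum(GenomicRanges::width(GenomicRanges::reduce(genome$mask)))
  structure(list(ptr = ptr, k = as.integer(k), genome = genome,
                 total_len = sum(Biostrings::width(genome$seqs)),
                 unmasked_len = unmasked),
            class = "GenomeIndex")
}

empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), raw_score = integer(0),
             bit_score = numeric(0), identity = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Find local-alignment hits of a query in a genome
#'
#' Seed-and-extend search on both strands: contiguous k-mer seeds are
#' grouped by diagonal and extended with an affine-gap local alignment.
#' Hits are filtered on percent identity and e-value, near-duplicate
#' placements within `merge_dist` bp on the same strand are merged (best
#' score kept), and results are ordered by bit-score (desc), then contig
#' name, then start, so ordering is deterministic.
#'
#' @param query nucleotide string (length >= seed length).
#' @param genome `GenomeSequence` (ignored when `index` given).
#' @param scheme `ScoringScheme`.
#' @param use_mask skip seeds falling wholly inside masked intervals
#'   (extension may still cross masked sequence).
#' @param index optional prebuilt [genome_index()].
#' @param merge_dist near-duplicate merge distance (bp).
#' @param two_hit require the seed evidence for a candidate region to span
#'   at least two seed lengths of the query before extension (the two-hit
#'   heuristic); the default for window-length queries. Disable for short
#'   tags, where a single seed is all the evidence a short read can carry.
#' @return data.frame of hits: contig, start, end (1-based closed), strand,
#'   raw_score, bit_score, identity, evalue.
#' @export
find_hits <- function(query, genome = NULL, scheme = scheme_pass1(),
                      use_mask = FALSE, index = NULL, merge_dist = 50L,
                      two_hit = TRUE) {
  if (is.null(index)) index <- genome_index(genome)
  if (nchar(query) < index$k)
    stop("query shorter than seed length (", index$k,
         "); use the short-read path")
  n <- if (use_mask) index$unmasked_len else index$total_len
  m <- nchar(query)
  min_raw <- min_raw_for_evalue(scheme, m, n)
  df <- cpp_find_hits(index$ptr, query, use_mask, two_hit, scheme$reward,
                      scheme$penalty, scheme$gap_open, scheme$gap_extend,
                      min_raw, as.integer(merge_dist))
  finish_hits(df, scheme, m, n)
}

finish_hits <- function(df, scheme, m, n) {
  if (nrow(df) == 0L) return(empty_hits())
  identity <- 100 * df$n_match / pmax(1L, df$aln_len)
  ev <- evalue_of(df$raw_score, scheme, m, n)
  keep <- identity >= scheme$min_identity & ev <= scheme$max_evalue
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(empty_hits())
  out <- data.frame(contig = df$contig, start = df$start + 1L,
                    end = df$end, strand = df$strand,
                    raw_score = df$raw_score,
                    bit_score = bit_score(df$raw_score, scheme),
                    identity = identity[keep], evalue = ev[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$bit_score, out$contig, out$start), , drop = FALSE]
}

#' Exhaustive local-alignment oracle
#'
#' Full Smith-Waterman/Gotoh optimum of `query` against `target` on both
#' strands, independent of the seeded search path. Capped at 1e8 DP cells.
#'
#' @param query,target nucleotide strings.
#' @param scheme `ScoringScheme` (only the score parameters are used).
#' @return list: raw_score, start, end (1-based closed on target), strand,
#'   identity.
#' @export
sw_oracle <- function(query, target, scheme = scheme_pass1()) {
  r <- cpp_sw_oracle(query, target, scheme$reward, scheme$penalty,
                     scheme$gap_open, scheme$gap_extend)
  list(raw_score = r$raw_score, start = r$start + 1L, end = r$end,
       strand = r$strand,
       identity = if (r$aln_len > 0) 100 * r$n_match / r$aln_len else NA_real_)
}
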