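#' Aligned RNA-Seq fragments
#'
#' @param contig,start,end fragment coordinates (1-based closed).
#' @param read_id fragment ids.
#' @param multimapped logical flag per fragment.
#' @return `GRanges` with `read_id` and `multimapped` metadata.
#' @export
aligned_fragments <- function(contig, start, end, read_id = NULL,
                              multimapped = FALSE) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end))
  gr$read_id <- if (is.null(read_id)) paste0("frag", seq_along(gr)) else
    as.character(read_id)
  gr$multimapped <- rep_len(multimapped, length(gr))
  gr
}

#' Read fragments from BED6+1 (extra column = multimap flag 0/1)
#' @param path BED file.
#' @export
read_fragments_bed <- function(path) {
  gr <- read_bed(path, extra_cols = "multimapped")
  aligned_fragments(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr), GenomicRanges::end(gr),
                    read_id = gr$name,
                    multimapped = as.logical(gr$multimapped %in%
                                               c(1, "1", TRUE)))
}

#' Per-gene fragment counts and FPKM
#'
#' A fragment counts for a gene when its interval overlaps the gene span,
#' it is not multimapped, and it overlaps no other gene (ambiguous
#' fragments are discarded, mirroring union-rule counting).
#' `FPKM = count * 1e9 / (exonic_length * library_size)`.
#'
#' @param fragments `GRanges` from [aligned_fragments()].
#' @param genes `GRanges` gene models with `exonic_length`.
#' @param library_size total mapped fragments (> 0).
#' @return data.frame: gene_id, count, fpkm.
#' @export
gene_counts_fpkm <- function(fragments, genes, library_size) {
  if (library_size <= 0) stop("library_size must be positive")
  hits <- GenomicRanges::findOverlaps(fragments, genes,
                                      ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  n_genes_per_frag <- tabulate(qi, length(fragments))
  usable <- n_genes_per_frag[qi] == 1L & !fragments$multimapped[qi]
  counts <- tabulate(S4Vectors::subjectHits(hits)[usable], length(genes))
  data.frame(gene_id = genes$gene_id, count = counts,
             fpkm = counts * 1e9 / (genes$exonic_length * library_size),
             stringsAsFactors = FALSE)
}

#' Windowed RNA-Seq coverage around mapped promoter midpoints
#'
#' Each mapped promoter's midpoint is extended 5 kb upstream and 20 kb
#' downstream in the 5'-to-3' orientation and the span divided into 250
#' non-overlapping 100-bp windows; a fragment increments every window its
#' interval overlaps. All fragments including multimappers are counted,
#' to capture qualitative expression within duplicated gene families.
#' Column 1 is always the 5'-most window (minus-strand rows are
#' reversed); the midpoint base falls in the window indexed by the
#' `midpoint_window` attribute (51 by construction).
#'
#' @param results MappingResults (only reported rows with a midpoint are
#'   used) or a data.frame with contig, midpoint, strand, promoter_id.
#' @param fragments `GRanges` of aligned fragments.
#' @param upstream,downstream,window_size span parameters (bp).
#' @return integer matrix (rows = promoters, 250 columns) with
#'   attributes `midpoint_window` and `contig`.
#' @export
window_coverage <- function(results, fragments, upstream = 5000L,
                            downstream = 20000L, window_size = 100L) {
  rows <- results[!is.na(results$midpoint), , drop = FALSE]
  n_win <- as.integer((upstream + downstream) / window_size)
  mat <- matrix(0L, nrow = nrow(rows), ncol = n_win,
                dimnames = list(rows$promoter_id, NULL))
  if (nrow(rows)) {
    mid <- rows$midpoint
    minus <- rows$strand == "-"
    # genomic left edge of the span in plus orientation; the minus-strand
    # grid is the exact mirror of the plus-strand one, so the midpoint
    # base sits in the midpoint window on both strands
    left <- ifelse(minus, mid - downstream + 1L, mid - upstream)
    starts <- rep(left, each = n_win) +
      (rep.int(seq_len(n_win), nrow(rows)) - 1L) * window_size
    wgr <- GenomicRanges::GRanges(rep(rows$contig, each = n_win),
                                  IRanges::IRanges(starts,
                                                   starts + window_size - 1L))
    cnt <- GenomicRanges::countOverlaps(wgr, fragments,
                                        ignore.strand = TRUE)
    mat <- matrix(as.integer(cnt), nrow = nrow(rows), ncol = n_win,
                  byrow = TRUE, dimnames = list(rows$promoter_id, NULL))
    if (any(minus))
      mat[minus, ] <- mat[minus, rev(seq_len(n_win)), drop = FALSE]
  }
  attr(mat, "midpoint_window") <- as.integer(upstream / window_size) + 1L
  attr(mat, "contig") <- rows$contig
  mat
}

#' Heatmap-eligible subset of a coverage matrix
#'
#' Keeps rows with at least `min_reads` summed over the first `span`
#' windows (the region covering the midpoint).
#'
#' @param mat matrix from [window_coverage()].
#' @param min_reads minimum summed reads (default 11).
#' @param span number of leading windows summed (default 100).
#' @return row-subset matrix (attributes preserved).
#' @export
heatmap_subset <- function(mat, min_reads = 11L, span = 100L) {
  keep <- rowSums(mat[, seq_len(min(span, ncol(mat))), drop = FALSE]) >=
    min_reads
  out <- mat[keep, , drop = FALSE]
  attr(out, "midpoint_window") <- attr(mat, "midpoint_window")
  attr(out, "contig") <- attr(mat, "contig")[keep]
  out
}

#' Per-promoter RNA-Seq expression-evidence call
#'
#' Evidence of nearby expression: at least `min_fpkm` in any of the seven
#' 100-bp windows spanning 200 bp upstream to 400 bp downstream of the
#' midpoint (windows m-2 .. m+4 where m is the midpoint window). Window
#' FPKM uses the window length as the per-kilobase denominator:
#' `count * 1e9 / (window_size * library_size)`.
#'
#' @param mat matrix from [window_coverage()].
#' @param library_size total mapped fragments.
#' @param min_fpkm threshold (default 1).
#' @param window_size window width in bp (default 100).
#' @return named logical vector (per row of `mat`).
#' @export
rnaseq_evidence_call <- function(mat, library_size, min_fpkm = 1,
                                 window_size = 100L) {
  m <- attr(mat, "midpoint_window")
  cols <- (m - 2L):(m + 4L)
  cols <- cols[cols >= 1L & cols <= ncol(mat)]
  sub <- mat[, cols, drop = FALSE]
  fpkm <- sub * 1e9 / (window_size * library_size)
  out <- apply(fpkm, 1L, max) >= min_fpkm
  setNames(as.logical(out), rownames(mat))
}

#' Integrate CAGE and RNA-Seq evidence per mapped promoter
#'
#' CAGE support: a CTSS cluster or a uniquely mapped singleton tag within
#' `max_dist` of the mapped promoter interval. RNA-Seq support: the
#' windowed expression call. Categories: both / cage_only / rnaseq_only /
#' none.
#'
#' @param promoters `GRanges` of mapped (extended) promoter intervals
#'   with a `promoter_id` metadata column.
#' @param clusters `GRanges` of supported CTSS clusters.
#' @param singleton_tags `GRanges` of uniquely mapped singleton tag
#'   placements (may be empty).
#' @param rnaseq_support named logical from [rnaseq_evidence_call()]
#'   (missing promoters count as unsupported).
#' @param max_dist proximity cutoff (default 2000).
#' @return list: `calls` data.frame (promoter_id, cage_support,
#'   rnaseq_support, category) and `summary` (fraction supported by
#'   either, and by both).
#' @export
integrate_evidence <- function(promoters, clusters,
                               singleton_tags = NULL, rnaseq_support,
                               max_dist = 2000L) {
  cage_feats <- clusters
  if (!is.null(singleton_tags) && length(singleton_tags)) {
    a <- GenomicRanges::granges(clusters)
    b <- GenomicRanges::granges(singleton_tags)
    cage_feats <- c(a, b)
  }
  cage <- IRanges::overlapsAny(promoters, cage_feats, maxgap = max_dist,
                               ignore.strand = TRUE)
  rna <- rnaseq_support[match(promoters$promoter_id,
                              names(rnaseq_support))]
  rna[is.na(rna)] <- FALSE
  category <- ifelse(cage & rna, "both",
                     ifelse(cage, "cage_only",
                            ifelse(rna, "rnaseq_only", "none")))
  calls <- data.frame(promoter_id = promoters$promoter_id,
                      cage_support = cage, rnaseq_support = rna,
                      category = category, stringsAsFactors = FALSE)
  list(calls = calls,
       summary = c(frac_supported = mean(cage | rna),
                   frac_both = mean(cage & rna),
                   frac_cage = mean(cage), frac_rnaseq = mean(rna)))
}
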