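#' @useDynLib promap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom methods is
#' @importFrom stats rbinom rnorm runif rmultinom setNames
#' @importFrom utils read.table write.table
NULL

DEFAULT_SCAFFOLD_PREFIXES <- c("GL", "JH", "scaffold", "AEMK")

#' In-memory genome with repeat mask and contig classification
#'
#' A `GenomeSequence` bundles the contig sequences (upper-cased), the
#' repeat mask as a set of intervals, and the classification of each contig
#' as a chromosome or an unplaced scaffold. The chromosome/scaffold split
#' drives the multimapper scaffold-rescue clause, and the mask restricts
#' seeding when promoters are projected onto a repeat-masked genome.
#'
#' @param seqs named character vector or `DNAStringSet` of contig sequences.
#' @param mask `GRanges` of masked (repeat) intervals, or `NULL`.
#' @param contig_class named character vector (`"chromosome"` or
#'   `"unplaced_scaffold"`) per contig; derived from `scaffold_prefixes`
#'   when omitted.
#' @param scaffold_prefixes contig-name prefixes classified as unplaced
#'   scaffolds when `contig_class` is not given.
#' @return An object of class `GenomeSequence`.
#' @export
genome_sequence <- function(seqs, mask = NULL, contig_class = NULL,
                            scaffold_prefixes = DEFAULT_SCAFFOLD_PREFIXES) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  nm <- names(seqs)
  if (length(seqs) && (is.null(nm) || anyNA(nm) || any(nm == "")))
    stop("all contigs must be named")
  if (length(seqs) == 0L) nm <- character(0)
  if (anyDuplicated(nm)) stop("duplicate contig name: ",
                              nm[duplicated(nm)][1L])
  if (is.null(mask)) mask <- GenomicRanges::GRanges()
  if (length(mask)) {
    bad <- !(as.character(GenomicRanges::seqnames(mask)) %in% nm)
    if (any(bad)) stop("mask interval on unknown contig")
    lens <- setNames(Biostrings::width(seqs), nm)
    if (any(GenomicRanges::end(mask) >
            lens[as.character(GenomicRanges::seqnames(mask))]) ||
        any(GenomicRanges::start(mask) < 1L))
      stop("mask interval out of contig bounds")
  }
  if (is.null(contig_class)) {
    is_scaf <- Reduce(`|`, lapply(scaffold_prefixes, function(p)
      startsWith(nm, p)), rep(FALSE, length(nm)))
    contig_class <- setNames(ifelse(is_scaf, "unplaced_scaffold",
                                    "chromosome"), nm)
  }
  stopifnot(all(nm %in% names(contig_class)))
  structure(list(seqs = seqs, mask = mask,
                 contig_class = contig_class[nm]),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence: %d contigs, %s bp total (%d masked intervals)\n",
              length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ","),
              length(x$mask)))
  invisible(x)
}

contig_lengths <- function(genome)
  setNames(Biostrings::width(genome$seqs), names(genome$seqs))

#' Read a genome FASTA with an optional repeat mask
#'
#' @param path FASTA file.
#' @param mask_mode `"lowercase"` (soft-masked bases become mask intervals),
#'   `"bed"` (mask read from `mask_bed`), or `"none"`.
#' @param mask_bed BED file of masked intervals when `mask_mode = "bed"`.
#' @param scaffold_prefixes passed to [genome_sequence()].
#' @return A `GenomeSequence`. Sequences are stored upper-case; case only
#'   carries the mask state on read.
#' @export
read_fasta <- function(path, mask_mode = c("lowercase", "bed", "none"),
                       mask_bed = NULL,
                       scaffold_prefixes = DEFAULT_SCAFFOLD_PREFIXES) {
  mask_mode <- match.arg(mask_mode)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) {
    warning("empty FASTA: ", path)
    return(genome_sequence(Biostrings::DNAStringSet(),
                           scaffold_prefixes = scaffold_prefixes))
  }
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate contig name in FASTA: ",
         names(raw)[duplicated(names(raw))][1L])
  chr <- as.character(raw)
  bad <- grepl("[^ACGTNacgtn]", chr)
  if (any(bad)) {
    sym <- regmatches(chr[bad][1L],
                      regexpr("[^ACGTNacgtn]", chr[bad][1L]))
    stop("unknown character in sequence '", names(raw)[bad][1L], "': '",
         sym, "'")
  }
  mask <- GenomicRanges::GRanges()
  if (mask_mode == "lowercase") {
    per <- lapply(seq_along(chr), function(i) {
      m <- gregexpr("[acgtn]+", chr[[i]])[[1L]]
      if (m[1L] == -1L) return(NULL)
      GenomicRanges::GRanges(names(raw)[i],
                             IRanges::IRanges(as.integer(m),
                                              width = attr(m, "match.length")))
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (length(per)) mask <- do.call(c, per)
  } else if (mask_mode == "bed") {
    if (is.null(mask_bed)) stop("mask_mode = 'bed' requires mask_bed")
    mask <- read_bed(mask_bed)
    S4Vectors::mcols(mask) <- NULL
  }
  genome_sequence(toupper(chr), mask = mask,
                  scaffold_prefixes = scaffold_prefixes)
}

#' Write intervals as BED
#'
#' Writes BED6 (0-based half-open) with optional extra metadata columns
#' appended after the strand column. Unstranded intervals get `"."`.
#'
#' @param gr `GRanges`; `name` and `score` metadata columns are used when
#'   present, extra columns named in `extra_cols` are appended.
#' @param path output file.
#' @param genome optional `GenomeSequence` for bounds checking.
#' @param extra_cols character vector of additional mcols to append.
#' @export
write_bed <- function(gr, path, genome = NULL, extra_cols = character()) {
  if (!is.null(genome) && length(gr)) {
    lens <- contig_lengths(genome)
    cn <- as.character(GenomicRanges::seqnames(gr))
    if (!all(cn %in% names(lens)) ||
        any(GenomicRanges::start(gr) < 1L) ||
        any(GenomicRanges::end(gr) > lens[cn]))
      stop("interval out of contig bounds")
  }
  mc <- S4Vectors::mcols(gr)
  nm <- if ("name" %in% colnames(mc)) as.character(mc$name) else
    rep(".", length(gr))
  sc <- if ("score" %in% colnames(mc)) mc$score else rep(0L, length(gr))
  st <- as.character(GenomicRanges::strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = sc, strand = st,
                   stringsAsFactors = FALSE)
  for (cc in extra_cols) df[[cc]] <- mc[[cc]]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' @param path BED3/BED6(+n) file.
#' @param extra_cols names for columns after the strand column, if any.
#' @return `GRanges` (1-based closed internally) with `name`, `score` and
#'   any extra columns as metadata.
#' @export
read_bed <- function(path, extra_cols = character()) {
  if (file.size(path) == 0L)
    return(GenomicRanges::GRanges(name = character(0), score = integer(0)))
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#",
                   quote = "")
  gr <- GenomicRanges::GRanges(
    df[[1L]],
    IRanges::IRanges(df[[2L]] + 1L, df[[3L]]),
    strand = if (ncol(df) >= 6L)
      ifelse(df[[6L]] == ".", "*", df[[6L]]) else "*")
  if (ncol(df) >= 4L) gr$name <- as.character(df[[4L]])
  if (ncol(df) >= 5L) gr$score <- df[[5L]]
  for (i in seq_along(extra_cols)) {
    col <- 6L + i
    if (ncol(df) >= col) S4Vectors::mcols(gr)[[extra_cols[i]]] <- df[[col]]
  }
  gr
}

#' Nearest feature within a distance cutoff
#'
#' Strand-agnostic nearest-feature lookup on a shared contig, with gap
#' semantics: overlapping intervals are at distance 0, otherwise the gap in
#' bases between the closest ends. Ties are broken by leftmost feature
#' start. Mirrors the behaviour of BEDTools closest with a distance cap.
#'
#' @param query `GRanges` of query intervals.
#' @param features `GRanges` of candidate features.
#' @param max_dist maximum gap (bp); features farther away are not returned.
#' @return data.frame with one row per query: `feature_idx` (index into
#'   `features`, `NA` when none within `max_dist`) and `distance`.
#' @export
closest_feature <- function(query, features, max_dist = 2000) {
  n <- length(query)
  out <- data.frame(feature_idx = rep(NA_integer_, n),
                    distance = rep(NA_integer_, n))
  if (n == 0L || length(features) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(query, features, maxgap = max_dist,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  gap <- pmax(0L,
              pmax(GenomicRanges::start(features)[fi] -
                     GenomicRanges::end(query)[qi] - 1L,
                   GenomicRanges::start(query)[qi] -
                     GenomicRanges::end(features)[fi] - 1L))
  keep <- gap <= max_dist
  qi <- qi[keep]; fi <- fi[keep]; gap <- gap[keep]
  if (!length(qi)) return(out)
  ord <- order(qi, gap, GenomicRanges::start(features)[fi], fi)
  first <- !duplicated(qi[ord])
  out$feature_idx[qi[ord][first]] <- fi[ord][first]
  out$distance[qi[ord][first]] <- gap[ord][first]
  out
}

#' Gene models with strand-aware 5' ends
#'
#' @param gene_id character vector of gene identifiers.
#' @param contig,start,end,strand gene span (1-based closed coordinates).
#' @param exonic_length exonic length in bp used as the FPKM denominator;
#'   defaults to the span length.
#' @return `GRanges` with `gene_id` and `exonic_length` metadata columns.
#' @export
gene_models <- function(gene_id, contig, start, end, strand,
                        exonic_length = NULL) {
  if (is.null(exonic_length)) exonic_length <- end - start + 1L
  stopifnot(all(exonic_length >= 1L))
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  gr$gene_id <- as.character(gene_id)
  gr$exonic_length <- as.integer(exonic_length)
  gr
}

#' Strand-aware 5'-end position of each gene
#' @param genes `GRanges` from [gene_models()].
#' @return integer vector of TSS positions (1-based).
#' @export
gene_tss <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}

#' Read gene models from BED6+1 (extra column = exonic length)
#' @param path file written by [write_gene_models()].
#' @export
read_gene_models <- function(path) {
  gr <- read_bed(path, extra_cols = "exonic_length")
  gene_models(gr$name, as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr), GenomicRanges::end(gr),
              as.character(GenomicRanges::strand(gr)),
              gr$exonic_length)
}

#' @rdname read_gene_models
#' @param genes `GRanges` of gene models.
#' @export
write_gene_models <- function(genes, path) {
  g <- genes
  g$name <- g$gene_id
  g$score <- 0L
  write_bed(g, path, extra_cols = "exonic_length")
}

#' Read / write an ortholog table
#'
#' TSV with header `source_gene<TAB>target_gene`; duplicate pairs are an
#' error. Lookup by source gene may return several target genes.
#'
#' @param path TSV file.
#' @return data.frame with columns `source_gene`, `target_gene`.
#' @export
read_orthologs <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  stopifnot(identical(colnames(df)[1:2], c("source_gene", "target_gene")))
  ortholog_table(df$source_gene, df$target_gene)
}

#' @rdname read_orthologs
#' @param source_gene,target_gene parallel vectors of orthologous gene ids.
#' @export
ortholog_table <- function(source_gene, target_gene) {
  df <- data.frame(source_gene = as.character(source_gene),
                   target_gene = as.character(target_gene),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop("duplicate ortholog pair")
  df
}

#' @rdname read_orthologs
#' @param orthologs data.frame from [ortholog_table()].
#' @export
write_orthologs <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Clip an interval to contig bounds
#' @param gr `GRanges`.
#' @param genome `GenomeSequence`.
#' @return `GRanges` with starts/ends clipped into `[1, contig length]`.
#' @export
clip_to_contig <- function(gr, genome) {
  lens <- contig_lengths(genome)
  cn <- as.character(GenomicRanges::seqnames(gr))
  GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr))
  GenomicRanges::end(gr) <- pmin(lens[cn], GenomicRanges::end(gr))
  gr
}

genome_subseq <- function(genome, contig, start, end) {
  as.character(Biostrings::subseq(genome$seqs[[contig]], start, end))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
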