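#' Promoter records around CAGE-defined TSS
#'
#' A promoter is a 501-bp window containing 400 bases upstream and 100
#' downstream of its main CAGE-defined TSS (the TSS base included).
#' Annotation classes follow the gene/ortholog association: `c11` = gene
#' with a target-species ortholog, `c10` = gene without one, `c00` = no
#' associated gene.
#'
#' @param promoter_id unique ids.
#' @param contig,tss,strand TSS coordinates (1-based) on the source genome.
#' @param gene_id associated gene id or `NA`.
#' @param has_target_ortholog logical; whether the gene has a known ortholog
#'   in the target species.
#' @param genome source `GenomeSequence` used to clip windows.
#' @return data.frame with window coordinates, `anno_class`,
#'   `edge_truncated` (window clipped below 501 bp) and `excluded`
#'   (clipped below 250 bp; dropped from projection).
#' @export
promoter_set <- function(promoter_id, contig, tss, strand,
                         gene_id = NA_character_,
                         has_target_ortholog = FALSE, genome = NULL) {
  n <- length(promoter_id)
  if (anyDuplicated(promoter_id)) stop("duplicate promoter_id")
  gene_id <- rep_len(as.character(gene_id), n)
  has_target_ortholog <- rep_len(has_target_ortholog, n) & !is.na(gene_id)
  w <- build_promoter_window(tss, strand, contig, genome)
  data.frame(promoter_id = as.character(promoter_id),
             contig = as.character(contig), tss = as.integer(tss),
             strand = as.character(strand), gene_id = gene_id,
             has_target_ortholog = has_target_ortholog,
             anno_class = ifelse(is.na(gene_id), "c00",
                                 ifelse(has_target_ortholog, "c11", "c10")),
             window_start = w$start, window_end = w$end,
             edge_truncated = w$edge_truncated, excluded = w$excluded,
             stringsAsFactors = FALSE)
}

#' Build the 501-bp promoter window around a TSS
#'
#' Plus strand: `[tss - 400, tss + 100]`; minus strand mirrored. Windows
#' are clipped to contig bounds; a clipped window is flagged
#' `edge_truncated`, and one shorter than 250 bp is flagged `excluded`
#' (dropped from projection).
#'
#' @param tss,strand,contig vectors of TSS positions (1-based), strands
#'   and contig names.
#' @param genome optional `GenomeSequence` for clipping.
#' @return data.frame: start, end, edge_truncated, excluded.
#' @export
build_promoter_window <- function(tss, strand, contig, genome = NULL) {
  minus <- strand == "-"
  start <- ifelse(minus, tss - 100L, tss - 400L)
  end <- ifelse(minus, tss + 400L, tss + 100L)
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    start <- pmax(1L, start)
    end <- pmin(lens[as.character(contig)], end)
  } else {
    start <- pmax(1L, start)
  }
  width <- end - start + 1L
  data.frame(start = as.integer(start), end = as.integer(end),
             edge_truncated = width < 501L, excluded = width < 250L)
}

#' Build the 2101-bp upstream window of a gene
#'
#' 2 kb upstream plus 101 bases including and downstream of the gene
#' 5'-end position, strand-aware, clipped to contig bounds.
#'
#' @param genes `GRanges` gene models.
#' @param genome `GenomeSequence` for clipping.
#' @return `GRanges` with `gene_id` and `truncated` metadata.
#' @export
build_ortholog_window <- function(genes, genome = NULL) {
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  start <- ifelse(minus, tss - 100L, tss - 2000L)
  end <- ifelse(minus, tss + 2000L, tss + 100L)
  start0 <- start
  start <- pmax(1L, start)
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    cn <- as.character(GenomicRanges::seqnames(genes))
    end0 <- end
    end <- pmin(lens[cn], end)
  } else end0 <- end
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                               IRanges::IRanges(unname(start), unname(end)),
                               strand = GenomicRanges::strand(genes))
  gr$gene_id <- genes$gene_id
  gr$truncated <- unname(start0 < 1L | end < end0)
  gr
}

promoter_query_seqs <- function(promoters, genome) {
  vapply(seq_len(nrow(promoters)), function(i) {
    s <- genome_subseq(genome, promoters$contig[i],
                       promoters$window_start[i], promoters$window_end[i])
    if (promoters$strand[i] == "-") revcomp_chr(s) else s
  }, character(1))
}

empty_result_row <- function(promoter_id, status, n_hits = 0L) {
  out <- data.frame(promoter_id = "x", status = "unmapped",
                    contig = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    raw_score = NA_integer_, bit_score = NA_real_,
                    n_hits = as.integer(n_hits)[1L],
                    midpoint = NA_integer_, stringsAsFactors = FALSE)
  if (length(promoter_id) == 0L) return(out[0L, , drop = FALSE])
  out$promoter_id <- promoter_id
  out$status <- status
  out$n_hits <- as.integer(n_hits)
  out
}

hit_result_row <- function(promoter_id, status, hit, n_hits) {
  len <- hit$end - hit$start + 1L
  data.frame(promoter_id = promoter_id, status = status,
             contig = hit$contig, start = hit$start, end = hit$end,
             strand = hit$strand, raw_score = hit$raw_score,
             bit_score = hit$bit_score, n_hits = as.integer(n_hits),
             midpoint = hit$start + len %/% 2L,
             stringsAsFactors = FALSE)
}

#' Multimapper rescue by bit-score ratio or scaffold tie-break
#'
#' Given hits ranked by bit-score (descending), the top hit is accepted
#' when the second-to-first bit-score ratio is below `ratio`. Failing
#' that, one hit is accepted when it lies on a chromosome and every other
#' hit lies on an unplaced scaffold. Otherwise the promoter (or tag)
#' stays multimapped.
#'
#' @param hits data.frame from [find_hits()] (bit-score sorted).
#' @param contig_class named vector classifying contigs as `"chromosome"`
#'   or `"unplaced_scaffold"`.
#' @param ratio score-ratio threshold (default 0.95).
#' @param scaffold_max_hits apply the scaffold clause only when the number
#'   of hits is at most this (default `Inf`; set 2 for the literal
#'   two-hit reading).
#' @return list: `hit` (single-row data.frame or `NULL`) and `status`
#'   (`"rescued_ratio"`, `"rescued_scaffold"` or `"multimapped"`).
#' @export
rescue_multimapped <- function(hits, contig_class, ratio = 0.95,
                               scaffold_max_hits = Inf) {
  stopifnot(nrow(hits) >= 2L)
  if (hits$bit_score[2L] / hits$bit_score[1L] < ratio)
    return(list(hit = hits[1L, , drop = FALSE], status = "rescued_ratio"))
  if (nrow(hits) <= scaffold_max_hits) {
    on_chr <- contig_class[hits$contig] == "chromosome"
    if (sum(on_chr) == 1L)
      return(list(hit = hits[which(on_chr), , drop = FALSE],
                  status = "rescued_scaffold"))
  }
  list(hit = NULL, status = "multimapped")
}

resolve_hits <- function(hits, contig_class, ratio = 0.95,
                         scaffold_max_hits = Inf) {
  if (nrow(hits) == 0L) return(list(hit = NULL, status = "unmapped"))
  if (nrow(hits) == 1L)
    return(list(hit = hits[1L, , drop = FALSE], status = "unique"))
  rescue_multimapped(hits, contig_class, ratio, scaffold_max_hits)
}

#' Map promoters onto the upstream windows of their orthologous genes
#'
#' Each promoter whose gene has at least one target-species ortholog is
#' aligned only against the 2101-bp upstream windows of those orthologs.
#' Any hit passing the identity/e-value cutoffs reports the promoter as
#' `ortholog_mapped` at the best bit-score placement (ties broken by
#' gene-id order). Promoters without a qualifying hit pass through to the
#' genome-wide stage.
#'
#' @param promoters data.frame from [promoter_set()].
#' @param queries character vector of window sequences (promoter-oriented);
#'   computed from `source_genome` when `NULL`.
#' @param source_genome,target_genome `GenomeSequence`s.
#' @param orthologs data.frame from [ortholog_table()].
#' @param target_genes `GRanges` gene models on the target genome.
#' @param scheme `ScoringScheme` (pass-1 scheme by default).
#' @return list: `results` (MappingResult rows for mapped promoters) and
#'   `pass_through` (promoter ids left for the genome-wide stage).
#' @export
map_via_orthology <- function(promoters, source_genome = NULL,
                              target_genome, orthologs, target_genes,
                              scheme = scheme_pass1(), queries = NULL) {
  if (is.null(queries)) queries <- promoter_query_seqs(promoters,
                                                       source_genome)
  owin <- build_ortholog_window(target_genes, target_genome)
  owin <- owin[order(owin$gene_id)]
  # one searchable mini-genome holding every ortholog upstream window;
  # hits are filtered per promoter to its own orthologs' windows
  wseqs <- vapply(seq_along(owin), function(j)
    genome_subseq(target_genome,
                  as.character(GenomicRanges::seqnames(owin))[j],
                  GenomicRanges::start(owin)[j],
                  GenomicRanges::end(owin)[j]), character(1))
  wnames <- paste0(owin$gene_id, "::w", seq_along(owin))
  wgenome <- genome_sequence(setNames(wseqs, wnames),
                             contig_class = setNames(
                               rep("chromosome", length(owin)), wnames))
  widx <- genome_index(wgenome)
  win_gene <- setNames(owin$gene_id, wnames)

  rows <- list()
  pass <- character(0)
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    if (is.na(p$gene_id) || !p$has_target_ortholog) {
      pass <- c(pass, p$promoter_id); next
    }
    tgt <- orthologs$target_gene[orthologs$source_gene == p$gene_id]
    if (!any(owin$gene_id %in% tgt)) { pass <- c(pass, p$promoter_id); next }
    hits <- find_hits(queries[i], scheme = scheme, index = widx)
    hits <- hits[win_gene[hits$contig] %in% tgt, , drop = FALSE]
    if (nrow(hits) == 0L) { pass <- c(pass, p$promoter_id); next }
    best <- hits[1L, , drop = FALSE] # bit-score desc, gene-id order ties
    wj <- match(best$contig, wnames)
    gstart <- GenomicRanges::start(owin)[wj]
    best$contig <- as.character(GenomicRanges::seqnames(owin))[wj]
    best$start <- gstart + best$start - 1L
    best$end <- gstart + best$end - 1L
    rows[[length(rows) + 1L]] <- hit_result_row(p$promoter_id,
                                                "ortholog_mapped", best, 1L)
  }
  list(results = if (length(rows)) do.call(rbind, rows) else
    empty_result_row(character(0), character(0)),
    pass_through = pass)
}

#' Project promoter windows onto a target genome
#'
#' Three stages: (1) orthology pass against the 2101-bp upstream windows
#' of known orthologs; (2) genome-wide pass with the tolerant scheme on
#' the repeat-masked genome, with multimapper rescue; (3) a second
#' genome-wide pass on the still-unmapped promoters with the strict
#' scheme, rescue applied the same way. Multimapped promoters from pass 2
#' stay multimapped (only unmapped promoters are re-aligned). Every
#' promoter receives exactly one MappingResult.
#'
#' @inheritParams map_via_orthology
#' @param scheme1,scheme2 pass-1 / pass-2 scoring schemes.
#' @param ratio multimapper bit-score-ratio threshold.
#' @param scaffold_max_hits see [rescue_multimapped()].
#' @param use_mask align against the repeat-masked target genome.
#' @param index optional prebuilt target [genome_index()].
#' @return data.frame of MappingResults: promoter_id, status (one of
#'   ortholog_mapped / unique / rescued_ratio / rescued_scaffold /
#'   multimapped / unmapped), chosen placement, n_hits and midpoint.
#' @export
project_promoters <- function(promoters, source_genome, target_genome,
                              orthologs = NULL, target_genes = NULL,
                              scheme1 = scheme_pass1(),
                              scheme2 = scheme_pass2(),
                              ratio = 0.95, scaffold_max_hits = Inf,
                              use_mask = TRUE, index = NULL) {
  act <- promoters[!promoters$excluded, , drop = FALSE]
  queries <- promoter_query_seqs(act, source_genome)
  names(queries) <- act$promoter_id

  rows <- list()
  remaining <- act$promoter_id
  if (!is.null(orthologs) && !is.null(target_genes) &&
      any(act$has_target_ortholog)) {
    om <- map_via_orthology(act, target_genome = target_genome,
                            orthologs = orthologs,
                            target_genes = target_genes,
                            scheme = scheme1, queries = queries)
    if (nrow(om$results)) rows[[length(rows) + 1L]] <- om$results
    remaining <- setdiff(remaining, om$results$promoter_id)
  }

  if (is.null(index)) index <- genome_index(target_genome)
  cls <- target_genome$contig_class

  run_pass <- function(ids, scheme) {
    unmapped <- character(0)
    for (pid in ids) {
      hits <- find_hits(queries[[pid]], scheme = scheme,
                        use_mask = use_mask, index = index)
      r <- resolve_hits(hits, cls, ratio, scaffold_max_hits)
      if (r$status == "unmapped") {
        unmapped <- c(unmapped, pid)
      } else if (is.null(r$hit)) {
        rows[[length(rows) + 1L]] <<- empty_result_row(pid, r$status,
                                                       nrow(hits))
      } else {
        rows[[length(rows) + 1L]] <<- hit_result_row(pid, r$status, r$hit,
                                                     nrow(hits))
      }
    }
    unmapped
  }

  unmapped1 <- run_pass(remaining, scheme1)
  unmapped2 <- run_pass(unmapped1, scheme2)
  for (pid in unmapped2)
    rows[[length(rows) + 1L]] <- empty_result_row(pid, "unmapped")
  for (pid in promoters$promoter_id[promoters$excluded])
    rows[[length(rows) + 1L]] <- empty_result_row(pid, "unmapped")

  res <- do.call(rbind, rows)
  res <- res[match(promoters$promoter_id, res$promoter_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reported-mapped predicate for MappingResults
#' @param results data.frame from [project_promoters()].
#' @return logical vector: TRUE when a placement was reported (not
#'   multimapped/unmapped).
#' @export
is_reported <- function(results)
  results$status %in% c("ortholog_mapped", "unique", "rescued_ratio",
                        "rescued_scaffold")

#' Is a mapped promoter within 20 kb upstream of its ortholog?
#'
#' TRUE when the chosen placement overlaps the strand-aware
#' `[tss - span, tss]` upstream window of the given target gene on the
#' same contig.
#'
#' @param results MappingResults (reported rows only are evaluated).
#' @param genes `GRanges` of the corresponding target orthologs, parallel
#'   to `results`.
#' @param span upstream extent in bp (default 20000).
#' @return logical vector parallel to `results`.
#' @export
within_upstream_of_ortholog <- function(results, genes, span = 20000L) {
  stopifnot(nrow(results) == length(genes))
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  up_start <- ifelse(minus, tss, pmax(1L, tss - span))
  up_end <- ifelse(minus, tss + span, tss)
  same_contig <- !is.na(results$contig) &
    results$contig == as.character(GenomicRanges::seqnames(genes))
  ok <- same_contig & is_reported(results) &
    results$start <= up_end & results$end >= up_start
  ok & !is.na(ok)
}
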