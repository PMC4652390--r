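#' Cross-species promoter classification
#'
#' Combines the projections of one promoter universe onto two target
#' genomes into per-promoter calls: `target1_specific` (reported in the
#' first target only), `target2_specific`, `both`, or `not_reported`
#' (reported in neither; includes unmapped and multimapped promoters).
#'
#' @param results1,results2 MappingResult data.frames over the same
#'   promoter universe.
#' @param promoters data.frame from [promoter_set()] carrying
#'   `anno_class` and `gene_id`.
#' @return list: `calls` (per-promoter data.frame) and `summary` (per
#'   anno_class x call counts, percents rounded half-up to whole percent,
#'   and distinct gene counts for the species-specific columns).
#' @export
classify <- function(results1, results2, promoters) {
  if (!setequal(results1$promoter_id, results2$promoter_id) ||
      nrow(results1) != nrow(results2))
    stop("result sets cover different promoter universes")
  results2 <- results2[match(results1$promoter_id, results2$promoter_id), ]
  promoters <- promoters[match(results1$promoter_id,
                               promoters$promoter_id), ]
  r1 <- is_reported(results1)
  r2 <- is_reported(results2)
  call <- ifelse(r1 & r2, "both",
                 ifelse(r1, "target1_specific",
                        ifelse(r2, "target2_specific", "not_reported")))
  calls <- data.frame(promoter_id = results1$promoter_id,
                      anno_class = promoters$anno_class,
                      gene_id = promoters$gene_id, call = call,
                      stringsAsFactors = FALSE)
  list(calls = calls, summary = class_summary(calls))
}

round_half_up <- function(x) floor(x + 0.5)

class_summary <- function(calls) {
  lvls <- c("target1_specific", "target2_specific", "both", "not_reported")
  per_class <- function(df, cls) {
    n <- nrow(df)
    cnt <- vapply(lvls, function(l) sum(df$call == l), integer(1))
    genes <- vapply(lvls, function(l) {
      g <- df$gene_id[df$call == l]
      length(unique(g[!is.na(g)]))
    }, integer(1))
    data.frame(anno_class = cls, call = lvls, count = cnt,
               percent = round_half_up(100 * cnt / max(1L, n)),
               n_genes = genes, class_total = n,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sort(unique(calls$anno_class)), function(cl)
    per_class(calls[calls$anno_class == cl, ], cl)))
  rbind(out, per_class(calls, "total"))
}

#' Gene-level rollup of promoters that failed to map
#'
#' `genes_tss`: genes with at least one associated promoter not reported
#' (unmapped or multimapped). `genes_none`: genes with all associated
#' promoters not reported. `genes_none` is always a subset of
#' `genes_tss`. Promoters without a gene association are ignored.
#'
#' @param results MappingResults.
#' @param promoters promoter set with `gene_id`.
#' @return list of two character vectors: `genes_tss`, `genes_none`.
#' @export
gene_rollup_unmapped <- function(results, promoters) {
  results <- results[match(promoters$promoter_id, results$promoter_id), ]
  keep <- !is.na(promoters$gene_id)
  g <- promoters$gene_id[keep]
  rep_ok <- is_reported(results)[keep]
  genes_tss <- sort(unique(g[!rep_ok]))
  all_un <- tapply(!rep_ok, g, all)
  genes_none <- sort(names(all_un)[all_un])
  list(genes_tss = genes_tss, genes_none = genes_none)
}

#' Non-redundant gene union across two source species
#'
#' Counts the distinct protein-coding genes covered by promoter mappings
#' from two source species, expressed in the second species' gene space:
#' the species-1 genes with mappings are converted through the ortholog
#' map (giving `species1_with_ortholog` ids), the extra species-2-only
#' ids are added, and the species-1 genes without any known ortholog are
#' appended since nothing can deduplicate them.
#'
#' @param species1_mapped number of species-1 gene ids with at least one
#'   mapped promoter.
#' @param species1_with_ortholog how many of those have a known species-2
#'   ortholog (must not exceed `species1_mapped`).
#' @param species2_extra species-2-only gene ids added by the second
#'   mapping set.
#' @return total distinct genes:
#'   `(species1_with_ortholog + species2_extra) +
#'    (species1_mapped - species1_with_ortholog)`.
#' @export
nonredundant_gene_union <- function(species1_mapped, species1_with_ortholog,
                                    species2_extra) {
  stopifnot(species1_mapped >= 0, species1_with_ortholog >= 0,
            species2_extra >= 0)
  if (species1_with_ortholog > species1_mapped)
    stop("orthologous count exceeds mapped count")
  converted <- species1_with_ortholog + species2_extra
  no_ortholog <- species1_mapped - species1_with_ortholog
  converted + no_ortholog
}

#' Set-based variant of the non-redundant gene union
#'
#' @param species1_ids,species2_ids character vectors of gene ids with at
#'   least one mapped promoter, in each species' own gene space.
#' @param orthologs data.frame mapping `source_gene` (species 1) to
#'   `target_gene` (species 2).
#' @return total distinct genes after converting species-1 ids through the
#'   ortholog map and deduplicating against the species-2 ids.
#' @export
nonredundant_gene_union_sets <- function(species1_ids, species2_ids,
                                         orthologs) {
  species1_ids <- unique(species1_ids)
  species2_ids <- unique(species2_ids)
  conv <- unique(orthologs$target_gene[orthologs$source_gene %in%
                                         species1_ids])
  has_orth <- species1_ids %in% orthologs$source_gene
  length(unique(c(conv, species2_ids))) + sum(!has_orth)
}

#' Genes with at least one reported promoter
#'
#' @param promoters promoter set with `gene_id`.
#' @param results MappingResults over the same universe.
#' @return list: `genes` (character vector, each gene counted once),
#'   `fraction` of the gene universe covered.
#' @export
at_least_one_mapped_tss <- function(promoters, results) {
  results <- results[match(promoters$promoter_id, results$promoter_id), ]
  keep <- !is.na(promoters$gene_id)
  g <- promoters$gene_id[keep]
  rep_ok <- is_reported(results)[keep]
  genes <- sort(unique(g[rep_ok]))
  universe <- unique(g)
  list(genes = genes,
       fraction = if (length(universe)) length(genes) / length(universe)
       else 0)
}
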