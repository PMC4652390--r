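#' Run configuration for the end-to-end pipeline
#'
#' Aggregates every stage's parameters with the pipeline's standard
#' defaults: 0.95 multimapper score ratio, 20-bp minimum tag length,
#' 11-bp trimming floor, 100 bp / 2 kb proximity cutoffs, the seven
#' evidence windows around the midpoint, and the 11-read heatmap filter.
#'
#' @param sim `SimConfig` for the synthetic inputs.
#' @param ratio,scaffold_max_hits multimapper-rescue parameters.
#' @param min_tag_len,trim_floor CAGE trimming parameters.
#' @param proximity proximity cutoffs in bp.
#' @param heatmap_min_reads heatmap row filter.
#' @param evidence_min_fpkm FPKM floor for the RNA-Seq evidence call.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(sim = sim_config(), ratio = 0.95,
                       scaffold_max_hits = Inf, min_tag_len = 20L,
                       trim_floor = 11L, proximity = c(100L, 2000L),
                       heatmap_min_reads = 11L, evidence_min_fpkm = 1) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the whole pipeline end-to-end on synthetic data
#'
#' Simulates a source genome with two target genomes (independent
#' mutation streams over the same source), projects the promoter set
#' onto both, classifies promoters across targets, processes the CAGE
#' library against target 1, computes RNA-Seq windowed coverage and
#' evidence calls, and integrates the evidence. All stage outputs and a
#' machine-readable summary are written under `out_dir`; rerunning with
#' the same config is bit-identical.
#'
#' @param config `RunConfig`.
#' @param out_dir output directory (created).
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_lines <- character(0)
  log_stage <- function(stage, values) {
    summary_lines <<- c(summary_lines, jsonlite::toJSON(
      c(list(stage = stage), values), auto_unbox = TRUE, digits = NA))
  }

  sim1 <- simulate_genome_pair(cfg$sim)
  sim2_cfg <- cfg$sim
  sim2_cfg$target_stream <- cfg$sim$target_stream + 1L
  sim2 <- simulate_genome_pair(sim2_cfg)
  log_stage("simulate", list(n_promoters = nrow(sim1$promoters),
                             n_genes = cfg$sim$n_genes))

  res1 <- project_promoters(sim1$promoters, sim1$source_genome,
                            sim1$target_genome, sim1$orthologs,
                            sim1$target_genes, ratio = cfg$ratio,
                            scaffold_max_hits = cfg$scaffold_max_hits)
  res2 <- project_promoters(sim2$promoters, sim2$source_genome,
                            sim2$target_genome, sim2$orthologs,
                            sim2$target_genes, ratio = cfg$ratio,
                            scaffold_max_hits = cfg$scaffold_max_hits)
  for (nm in c("1", "2")) {
    r <- if (nm == "1") res1 else res2
    log_stage(paste0("project_target", nm),
              as.list(table(r$status)))
  }
  write_mapping_results(res1, file.path(out_dir, "mappings_target1.tsv"))
  write_mapping_results(res2, file.path(out_dir, "mappings_target2.tsv"))

  cls <- classify(res1, res2, sim1$promoters)
  write.table(cls$calls, file.path(out_dir, "cross_species_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- summarize_mapping_table(cls)
  write.table(tab, file.path(out_dir, "mapping_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage("classify", as.list(table(cls$calls$call)))

  reads <- simulate_cage_fastq(sim1)
  cage <- cage_pipeline(reads, sim1$target_genome,
                        adapter_3p = cfg$sim$adapter_3p,
                        prefix_5p_len = nchar(cfg$sim$prefix_5p),
                        min_len = cfg$min_tag_len, ratio = cfg$ratio,
                        scaffold_max_hits = cfg$scaffold_max_hits,
                        floor_len = cfg$trim_floor)
  ctss <- cage$clusters_supported
  ctss$name <- paste0("ctss", seq_along(ctss))
  ctss$score <- ctss$tag_count
  write_bed(ctss, file.path(out_dir, "ctss_clusters.bed"))
  log_stage("cage", as.list(cage$stats))

  rna <- simulate_rnaseq_fragments(sim1)
  mapped1 <- res1[is_reported(res1), , drop = FALSE]
  mat <- window_coverage(mapped1, rna$fragments)
  rna_call <- rnaseq_evidence_call(mat, rna$library_size,
                                   min_fpkm = cfg$evidence_min_fpkm)
  fpkm <- gene_counts_fpkm(rna$fragments, sim1$target_genes,
                           rna$library_size)
  write.table(fpkm, file.path(out_dir, "gene_fpkm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage("rnaseq", list(library_size = rna$library_size,
                           n_supported = sum(rna_call)))

  mp <- GenomicRanges::GRanges(mapped1$contig,
                               IRanges::IRanges(mapped1$start,
                                                mapped1$end),
                               strand = mapped1$strand)
  mp$promoter_id <- mapped1$promoter_id
  singles <- cage$clusters[cage$clusters$tag_count == 1L]
  ev <- integrate_evidence(mp, ctss, singles, rna_call,
                           max_dist = max(cfg$proximity))
  write.table(ev$calls, file.path(out_dir, "evidence_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prox <- promoter_ctss_proximity(ctss, mp, d = cfg$proximity)
  write.table(prox, file.path(out_dir, "ctss_proximity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log_stage("integrate", as.list(ev$summary))

  writeLines(summary_lines, file.path(out_dir, "summary.jsonl"))
  invisible(list(sim1 = sim1, sim2 = sim2, res1 = res1, res2 = res2,
                 classification = cls, cage = cage, coverage = mat,
                 rnaseq_call = rna_call, evidence = ev,
                 proximity = prox))
}

write_mapping_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Mapping-statistics table across two target species
#'
#' One row per annotation class plus a total row; columns give the
#' promoter counts (with bracketed percents) mapped specifically to each
#' target, to both, and not reported, plus distinct associated gene
#' counts for the species-specific columns. Percent cells recompute
#' exactly from the count cells.
#'
#' @param classification output of [classify()].
#' @return data.frame in the table layout.
#' @export
summarize_mapping_table <- function(classification) {
  s <- classification$summary
  wide <- do.call(rbind, lapply(split(s, s$anno_class), function(d) {
    g <- function(call, col) d[[col]][d$call == call]
    data.frame(
      anno_class = d$anno_class[1L],
      target1_specific = sprintf("%d [%d%%]", g("target1_specific", "count"),
                                 g("target1_specific", "percent")),
      genes1 = g("target1_specific", "n_genes"),
      target2_specific = sprintf("%d [%d%%]", g("target2_specific", "count"),
                                 g("target2_specific", "percent")),
      genes2 = g("target2_specific", "n_genes"),
      both = sprintf("%d [%d%%]", g("both", "count"), g("both", "percent")),
      not_reported = sprintf("%d [%d%%]", g("not_reported", "count"),
                             g("not_reported", "percent")),
      total = d$class_total[1L],
      stringsAsFactors = FALSE)
  }))
  ord <- c(setdiff(sort(unique(s$anno_class)), "total"), "total")
  wide <- wide[match(ord, wide$anno_class), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}
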