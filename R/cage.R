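#' Trim raw CAGE reads
#'
#' Removes the fixed-length 5' prefix (barcode + restriction enzyme
#' sequence), then locates the 3' adapter by best suffix overlap
#' (leftmost start with overlap >= 3 bp and at most one mismatch per 10
#' bases of overlap) and removes it. Reads shorter than `min_len` after
#' trimming are dropped. No base-quality filtering is applied.
#'
#' @param reads named character vector of read sequences, or a FASTQ path.
#' @param adapter_3p 3' adapter sequence.
#' @param prefix_5p_len length of the fixed 5' prefix to remove.
#' @param min_len minimum kept length (default 20).
#' @return data.frame of tags: `read_id`, `seq`; attribute `retention`
#'   holds the kept fraction.
#' @export
trim_reads <- function(reads, adapter_3p, prefix_5p_len, min_len = 20L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_seqs(reads)
  n0 <- length(reads)
  if (n0 == 0L) {
    warning("no reads to trim")
    out <- data.frame(read_id = character(0), seq = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "retention") <- NA_real_
    return(out)
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  body <- substring(reads, prefix_5p_len + 1L)
  keep_len <- cpp_trim_adapter(body, adapter_3p, 3L)
  tags <- substr(body, 1L, keep_len)
  keep <- nchar(tags) >= min_len
  out <- data.frame(read_id = ids[keep], seq = tags[keep],
                    stringsAsFactors = FALSE)
  attr(out, "retention") <- sum(keep) / n0
  out
}

read_fastq_seqs <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Align CAGE tags to a genome and resolve their mapping class
#'
#' Tags are aligned on both strands of the (unmasked) genome; terminal
#' mismatches are absorbed by the local alignment, emulating soft
#' clipping of up to a couple of bases at each end. Each tag is resolved
#' to `unique` (single placement, or multimapper resolved by the 0.95
#' bit-score-ratio rule or the chromosome-vs-scaffold tie-break),
#' `multimapped`, or `unmapped`.
#'
#' @param tags data.frame from [trim_reads()] (columns read_id, seq).
#' @param genome `GenomeSequence` (ignored if `index` given).
#' @param scheme `ScoringScheme` (default [scheme_tags()]).
#' @param index prebuilt [genome_index()] of the (unmasked) genome.
#' @param ratio score-ratio threshold.
#' @param soft_clip maximum unaligned bases tolerated at each tag end
#'   (default 2).
#' @param scaffold_max_hits see [rescue_multimapped()].
#' @return `tags` with columns added: `map_class`, `contig`, `start`,
#'   `end`, `strand`, `n_hits`, `trim_iterations` (0 here).
#' @export
align_cage_tags <- function(tags, genome = NULL, scheme = scheme_tags(),
                            index = NULL, ratio = 0.95,
                            scaffold_max_hits = Inf, soft_clip = 2L) {
  if (is.null(index)) index <- genome_index(genome)
  res <- resolve_tags_batch(tags$seq, index, scheme, ratio,
                            scaffold_max_hits, soft_clip)
  cbind(tags[, c("read_id", "seq")], res,
        data.frame(trim_iterations = rep(0L, nrow(tags))))
}

# Batch alignment + resolution for many tags; vectorized over the common
# cases (0 or 1 hit), looping only over multimappers that fail the ratio
# rule. Soft clipping is capped at `soft_clip` bases per end: placements
# leaving more of the tag unaligned are rejected.
resolve_tags_batch <- function(seqs, index, scheme, ratio = 0.95,
                               scaffold_max_hits = Inf, soft_clip = 2L) {
  n <- length(seqs)
  out <- data.frame(map_class = rep("unmapped", n),
                    contig = NA_character_, start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    n_hits = 0L, stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  too_short <- nchar(seqs) < index$k
  ok <- which(!too_short)
  if (!length(ok)) return(out)
  m <- nchar(seqs[ok])
  gn <- index$total_len
  min_raw <- min_raw_for_evalue(scheme, min(m), gn)
  h <- cpp_align_tags(index$ptr, seqs[ok], FALSE, FALSE, scheme$reward,
                      scheme$penalty, scheme$gap_open, scheme$gap_extend,
                      min_raw, 25L)
  if (!length(h$tag_idx)) return(out)
  hd <- data.frame(tag_idx = h$tag_idx, contig = h$contig,
                   start = h$start + 1L, end = h$end, strand = h$strand,
                   raw_score = h$raw_score, n_match = h$n_match,
                   aln_len = h$aln_len, q_start = h$q_start,
                   q_end = h$q_end, stringsAsFactors = FALSE)
  identity <- 100 * hd$n_match / pmax(1L, hd$aln_len)
  ev <- evalue_of(hd$raw_score, scheme, m[hd$tag_idx], gn)
  clip_ok <- hd$q_start <= soft_clip &
    (m[hd$tag_idx] - hd$q_end) <= soft_clip
  hd <- hd[identity >= scheme$min_identity & ev <= scheme$max_evalue &
             clip_ok, , drop = FALSE]
  if (!nrow(hd)) return(out)
  hd <- hd[order(hd$tag_idx, -hd$raw_score, hd$contig, hd$start), ,
           drop = FALSE]
  counts <- tabulate(hd$tag_idx, length(ok))
  out$n_hits[ok] <- counts

  first <- which(!duplicated(hd$tag_idx))
  f <- hd[first, , drop = FALSE]
  ti <- f$tag_idx

  take <- function(rows, which_tags, cls) {
    gi <- ok[which_tags]
    out$map_class[gi] <<- cls
    out$contig[gi] <<- rows$contig
    out$start[gi] <<- rows$start
    out$end[gi] <<- rows$end
    out$strand[gi] <<- rows$strand
  }

  single <- counts[ti] == 1L
  take(f[single, , drop = FALSE], ti[single], "unique")

  multi <- which(counts[ti] >= 2L)
  if (length(multi)) {
    s1 <- f[multi, , drop = FALSE]
    s2 <- hd[first[multi] + 1L, , drop = FALSE]
    b1 <- bit_score(s1$raw_score, scheme)
    b2 <- bit_score(s2$raw_score, scheme)
    ratio_ok <- b2 / b1 < ratio
    take(s1[ratio_ok, , drop = FALSE], s1$tag_idx[ratio_ok], "unique")
    cls <- index$genome$contig_class
    for (i in which(!ratio_ok)) {
      tg <- s1$tag_idx[i]
      if (counts[tg] > scaffold_max_hits) {
        out$map_class[ok[tg]] <- "multimapped"; next
      }
      rows <- hd[hd$tag_idx == tg, , drop = FALSE]
      on_chr <- cls[rows$contig] == "chromosome"
      if (sum(on_chr) == 1L) {
        take(rows[which(on_chr), , drop = FALSE], tg, "unique")
      } else out$map_class[ok[tg]] <- "multimapped"
    }
  }
  out
}

#' Iterative end-trimming rescue of unmapped tags
#'
#' Each iteration removes one base from the 5' end and one from the 3'
#' end of every still-unresolved tag and realigns, stopping when a single
#' placement is found (directly, or via the ratio/scaffold rules) or when
#' the next trim would take the tag below `floor_len` (11 bp, the
#' shortest unique substring length observed in mammalian genomes).
#' Tags rescued this way get `map_class = "rescued"`; tags ending with
#' multiple equivalent placements are `multimapped`; the rest stay
#' `unmapped`. Multimapped tags from the initial alignment are not
#' re-trimmed.
#'
#' @param tags data.frame from [align_cage_tags()].
#' @param genome,scheme,index,ratio,scaffold_max_hits as in
#'   [align_cage_tags()].
#' @param floor_len minimum tag length eligible for realignment.
#' @return `tags` with rescued placements filled in and
#'   `trim_iterations` recording the iteration of rescue.
#' @export
iterative_trim_rescue <- function(tags, genome = NULL,
                                  scheme = scheme_tags(), index = NULL,
                                  ratio = 0.95, scaffold_max_hits = Inf,
                                  floor_len = 11L, soft_clip = 2L) {
  if (is.null(index)) index <- genome_index(genome)
  active <- which(tags$map_class == "unmapped")
  seqs <- tags$seq[active]
  iter <- 0L
  while (length(active)) {
    can <- nchar(seqs) - 2L >= floor_len
    active <- active[can]
    seqs <- seqs[can]
    if (!length(active)) break
    iter <- iter + 1L
    seqs <- substr(seqs, 2L, nchar(seqs) - 1L)
    res <- resolve_tags_batch(seqs, index, scheme, ratio,
                              scaffold_max_hits, soft_clip)
    placed <- res$map_class == "unique"
    if (any(placed)) {
      gi <- active[placed]
      tags$map_class[gi] <- "rescued"
      tags$contig[gi] <- res$contig[placed]
      tags$start[gi] <- res$start[placed]
      tags$end[gi] <- res$end[placed]
      tags$strand[gi] <- res$strand[placed]
      tags$n_hits[gi] <- res$n_hits[placed]
      tags$trim_iterations[gi] <- iter
    }
    # multimapped-at-this-length tags keep iterating; record their state
    # in case they never resolve.
    multi <- res$map_class == "multimapped"
    tags$map_class[active[multi]] <- "multimapped"
    tags$trim_iterations[active[multi]] <- iter
    tags$n_hits[active[multi]] <- res$n_hits[multi]
    keep <- !placed
    active <- active[keep]
    seqs <- seqs[keep]
    # tags flagged multimapped stay active: a further trim may separate
    # near-identical loci? No - trimming only loses information, so stop
    # trimming multimapped tags, matching the single-location stop rule.
    still <- tags$map_class[active] == "unmapped"
    active <- active[still]
    seqs <- seqs[still]
  }
  tags
}

#' Extend a placement symmetrically to promoter length
#'
#' Total added bases = `target_len - width`, split half-and-half with the
#' odd base going to the 5' side (strand-aware), then clipped to contig
#' bounds (so edge placements may stay shorter than `target_len`).
#' Placements already longer than `target_len` are returned unchanged
#' with a warning.
#'
#' @param gr stranded `GRanges` of tag (or promoter) placements.
#' @param target_len extended length (default 501).
#' @param genome `GenomeSequence` for clipping.
#' @return extended `GRanges`.
#' @export
extend_to_promoter_length <- function(gr, target_len = 501L,
                                      genome = NULL) {
  w <- GenomicRanges::width(gr)
  if (any(w > target_len)) {
    warning(sum(w > target_len), " placement(s) already longer than ",
            target_len, " bp left unchanged")
  }
  add <- pmax(0L, target_len - w)
  five <- as.integer(ceiling(add / 2))
  three <- add - five
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  new_start <- ifelse(minus, GenomicRanges::start(gr) - three,
                      GenomicRanges::start(gr) - five)
  new_end <- ifelse(minus, GenomicRanges::end(gr) + five,
                    GenomicRanges::end(gr) + three)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(pmax(1L, new_start),
                                                 new_end),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  if (!is.null(genome)) out <- clip_to_contig(out, genome)
  out
}

#' Cluster extended CAGE tag placements into CTSS clusters
#'
#' Single-linkage merge of placements overlapping by at least one base,
#' per contig and per strand (abutting intervals are NOT merged). The
#' cluster interval is the union of its members and `tag_count` the
#' number of supporting tags. Singleton removal is a separate, reported
#' step ([drop_singletons()]).
#'
#' @param placements stranded `GRanges` of extended tag placements.
#' @return `GRanges` of clusters with `tag_count`.
#' @export
cluster_ctss <- function(placements) {
  cl <- GenomicRanges::reduce(placements, min.gapwidth = 0L,
                              ignore.strand = FALSE)
  cl$tag_count <- GenomicRanges::countOverlaps(cl, placements,
                                               ignore.strand = FALSE)
  cl
}

#' @rdname cluster_ctss
#' @param clusters `GRanges` from [cluster_ctss()].
#' @export
drop_singletons <- function(clusters) clusters[clusters$tag_count >= 2L]

#' Assign CTSS clusters to genes
#'
#' A cluster is assigned to a gene when it overlaps the gene span or the
#' strand-aware 2-kb upstream window. When several genes qualify, the one
#' whose 5' end is nearest to the cluster wins.
#'
#' @param clusters `GRanges` of CTSS clusters.
#' @param genes `GRanges` gene models.
#' @param upstream upstream extent (default 2000 bp).
#' @return character vector (per cluster) of gene ids, `NA` when
#'   unassigned.
#' @export
cluster_gene_assignment <- function(clusters, genes, upstream = 2000L) {
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  reg <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(genes),
    IRanges::IRanges(pmax(1L, ifelse(minus, GenomicRanges::start(genes),
                                     GenomicRanges::start(genes) - upstream)),
                     ifelse(minus, GenomicRanges::end(genes) + upstream,
                            GenomicRanges::end(genes))))
  hits <- GenomicRanges::findOverlaps(clusters, reg, ignore.strand = TRUE)
  out <- rep(NA_character_, length(clusters))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  mid <- (GenomicRanges::start(clusters)[qi] +
            GenomicRanges::end(clusters)[qi]) %/% 2L
  d5 <- abs(mid - tss[fi])
  ord <- order(qi, d5, fi)
  keep <- !duplicated(qi[ord])
  out[qi[ord][keep]] <- genes$gene_id[fi[ord][keep]]
  out
}

#' Mutual proximity between CTSS clusters and mapped promoters
#'
#' Reports, at each distance cutoff, the fraction of clusters within the
#' cutoff of a mapped promoter and the fraction of mapped promoters
#' within the cutoff of a cluster (gap semantics: overlap = distance 0).
#'
#' @param clusters `GRanges` of CTSS clusters.
#' @param promoters `GRanges` of mapped (extended) promoter intervals.
#' @param d distance cutoffs in bp.
#' @return data.frame: d, cluster_to_promoter, promoter_to_cluster.
#' @export
promoter_ctss_proximity <- function(clusters, promoters,
                                    d = c(100L, 2000L)) {
  do.call(rbind, lapply(d, function(dd) {
    data.frame(
      d = dd,
      cluster_to_promoter =
        mean(IRanges::overlapsAny(clusters, promoters, maxgap = dd,
                                  ignore.strand = TRUE)),
      promoter_to_cluster =
        mean(IRanges::overlapsAny(promoters, clusters, maxgap = dd,
                                  ignore.strand = TRUE)))
  }))
}

#' Full CAGE processing pipeline
#'
#' Trim, length-filter, align, iteratively rescue, extend to promoter
#' length and cluster into CTSS clusters.
#'
#' @param reads FASTQ path or named character vector of raw reads.
#' @param genome target `GenomeSequence`.
#' @param adapter_3p,prefix_5p_len,min_len trimming parameters.
#' @param scheme tag scoring scheme.
#' @param ratio,scaffold_max_hits,floor_len mapping-resolution parameters.
#' @return list: `tags` (with map_class and placements), `placements`
#'   (GRanges of uniquely placed tags incl. rescued), `extended`,
#'   `clusters` (all CTSS clusters), `clusters_supported` (singletons
#'   removed), `stats`.
#' @export
cage_pipeline <- function(reads, genome, adapter_3p, prefix_5p_len,
                          min_len = 20L, scheme = scheme_tags(),
                          ratio = 0.95, scaffold_max_hits = Inf,
                          floor_len = 11L) {
  tags <- trim_reads(reads, adapter_3p, prefix_5p_len, min_len)
  retention <- attr(tags, "retention")
  idx <- genome_index(genome)
  tags <- align_cage_tags(tags, index = idx, scheme = scheme,
                          ratio = ratio,
                          scaffold_max_hits = scaffold_max_hits)
  tags <- iterative_trim_rescue(tags, index = idx, scheme = scheme,
                                ratio = ratio,
                                scaffold_max_hits = scaffold_max_hits,
                                floor_len = floor_len)
  placed <- tags[tags$map_class %in% c("unique", "rescued"), ,
                 drop = FALSE]
  placements <- GenomicRanges::GRanges(placed$contig,
                                       IRanges::IRanges(placed$start,
                                                        placed$end),
                                       strand = placed$strand)
  placements$read_id <- placed$read_id
  extended <- extend_to_promoter_length(placements, 501L, genome)
  clusters <- cluster_ctss(extended)
  supported <- drop_singletons(clusters)
  stats <- c(n_reads_kept = nrow(tags),
             retention = retention,
             n_unique = sum(tags$map_class == "unique"),
             n_rescued = sum(tags$map_class == "rescued"),
             n_multimapped = sum(tags$map_class == "multimapped"),
             n_unmapped = sum(tags$map_class == "unmapped"),
             n_clusters = length(clusters),
             n_singletons = length(clusters) - length(supported),
             n_clusters_supported = length(supported))
  list(tags = tags, placements = placements, extended = extended,
       clusters = clusters, clusters_supported = supported,
       stats = stats)
}
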