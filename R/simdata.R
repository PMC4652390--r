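#' Configuration for the synthetic genome-pair generator
#'
#' Defines the study conditions the simulator emulates: conserved
#' promoter windows at a configurable divergence, short repeat insertions
#' interrupting promoter homology, verbatim duplicated loci (optionally
#' placed on unplaced scaffolds), sharp versus broad TSS tag
#' distributions, and gene-proportional RNA-Seq coverage.
#'
#' @param seed master seed; per-component streams are derived from it so
#'   stages can be re-simulated independently.
#' @param n_genes number of gene loci.
#' @param contig_layout data.frame with columns name, length, class
#'   (`"chromosome"` / `"unplaced_scaffold"`).
#' @param gene_len gene-body length in bp.
#' @param promoter_divergence per-base substitution rate applied to the
#'   target copy of each locus (0..1).
#' @param indel_rate per-base insertion+deletion rate.
#' @param repeat_prob probability that a target promoter window receives
#'   a repeat insertion (recorded in the target mask).
#' @param repeat_len_range length range of inserted repeats.
#' @param duplication_fraction fraction of target loci copied verbatim to
#'   a second location.
#' @param scaffold_copy_fraction fraction of those copies placed on an
#'   unplaced scaffold (the rest go elsewhere on a chromosome).
#' @param ortholog_fraction fraction of source genes given a known target
#'   ortholog.
#' @param gene_assoc_fraction fraction of promoters carrying a gene
#'   association (the rest are class c00).
#' @param sharp_fraction fraction of promoters with a sharp (point-mass)
#'   TSS; the rest are broad.
#' @param broad_sd standard deviation (bp) of tag 5' ends for broad TSS.
#' @param cage_depth,rnaseq_depth read/fragment counts.
#' @param cage_unalignable fraction of CAGE reads made random
#'   (unalignable) sequence.
#' @param cage_error fraction of sharp-promoter tags whose 5' end is
#'   jittered by a few bp.
#' @param prefix_5p,adapter_3p,read_len CAGE library construction
#'   constants (36-bp reads carrying a 5' barcode+enzyme prefix and a
#'   3' adapter).
#' @param frag_len RNA-Seq fragment length.
#' @param target_stream integer stream id for the target-genome
#'   mutations: two configs differing only here share the identical
#'   source genome, giving two target species for one promoter universe.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L,
                       contig_layout = data.frame(
                         name = c("chr1", "scaffold_1"),
                         length = c(215000L, 15000L),
                         class = c("chromosome", "unplaced_scaffold"),
                         stringsAsFactors = FALSE),
                       gene_len = 400L,
                       promoter_divergence = 0.05, indel_rate = 0.002,
                       repeat_prob = 0.10,
                       repeat_len_range = c(50L, 200L),
                       duplication_fraction = 0.05,
                       scaffold_copy_fraction = 0.5,
                       ortholog_fraction = 0.8,
                       gene_assoc_fraction = 0.9,
                       sharp_fraction = 0.7, broad_sd = 20,
                       cage_depth = 50000L, rnaseq_depth = 100000L,
                       cage_unalignable = 0.05, cage_error = 0.02,
                       prefix_5p = "CAGTACGT",
                       adapter_3p = "AGATCGGAAGAGC", read_len = 36L,
                       frag_len = 150L, target_stream = 1L) {
  rates <- c(promoter_divergence, indel_rate, repeat_prob,
             duplication_fraction, scaffold_copy_fraction,
             ortholog_fraction, gene_assoc_fraction, sharp_fraction,
             cage_unalignable, cage_error)
  stopifnot(all(rates >= 0 & rates <= 1), all(contig_layout$length > 0),
            n_genes >= 1, gene_len >= 101L)
  structure(as.list(environment()), class = "SimConfig")
}

# Independent RNG stream per component, derived from the master seed.
stream_seed <- function(seed, name, extra = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + extra * 31337) %%
               2147483647)
}

with_stream <- function(seed, name, extra = 0L, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name, extra))
  expr
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

REPEAT_MOTIFS <- c("GGCCAATGGCCA", "TTAGGGTTAGGG", "ACACACAC")

# Mutate a sequence: uniform per-base substitutions plus sparse 1-bp
# indels. Returns the new sequence and the image of every original
# position (NA for deleted bases).
mutate_seq <- function(seq, sub_rate, indel_rate) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  del <- runif(n) < indel_rate / 2
  ins <- runif(n) < indel_rate / 2
  keep <- !del
  sub <- keep & runif(n) < sub_rate
  if (any(sub)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    b[sub] <- vapply(strsplit(unname(alt[b[sub]]), ""), function(ch)
      ch[sample.int(3L, 1L)], character(1))
  }
  A <- cumsum(as.integer(keep) + as.integer(ins))
  new_len <- A[n]
  out <- character(new_len)
  map <- rep(NA_integer_, n)
  kept_pos <- A[keep] - as.integer(ins[keep])
  out[kept_pos] <- b[keep]
  map[keep] <- kept_pos
  if (any(ins))
    out[A[ins]] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
  list(seq = paste(out, collapse = ""), map = map)
}

#' Simulate a homologous source/target genome pair with ground truth
#'
#' Builds a source genome of gene loci (each locus: 400 bp of upstream
#' promoter sequence, the TSS, and a gene body) separated by random
#' spacers, then derives a target genome whose loci are mutated copies at
#' the configured substitution/indel rates with independent intergenic
#' sequence. A configurable fraction of target loci is duplicated
#' verbatim (some copies on an unplaced scaffold), repeat motifs may be
#' inserted into target promoter windows (and recorded in the target
#' mask), and a configurable fraction of genes receives a known ortholog.
#'
#' @param config `SimConfig`.
#' @return list: `source_genome`, `target_genome` (`GenomeSequence`),
#'   `promoters` (from [promoter_set()]), `source_genes`, `target_genes`
#'   (`GRanges`), `orthologs`, and `truth` (per-promoter data.frame with
#'   expected target interval/TSS, expected status, duplication/repeat
#'   flags, TSS shape and expression level).
#' @export
simulate_genome_pair <- function(config) {
  cfg <- config
  chroms <- cfg$contig_layout$name[cfg$contig_layout$class == "chromosome"]
  scafs <- cfg$contig_layout$name[cfg$contig_layout$class ==
                                    "unplaced_scaffold"]
  if (!length(chroms)) stop("layout needs at least one chromosome")
  main <- chroms[1L]
  main_len <- cfg$contig_layout$length[cfg$contig_layout$name == main]
  core_len <- 400L + cfg$gene_len
  n <- cfg$n_genes

  src <- with_stream(cfg$seed, "source", 0L, {
    spacers <- sample(80:160, n, replace = TRUE)
    cores <- vapply(seq_len(n), function(i) random_dna(core_len),
                    character(1))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    need <- sum(spacers) + n * core_len
    if (need > main_len)
      stop("contig layout too small to place ", n, " gene loci (need ",
           need, " bp)")
    fill <- random_dna(main_len - need)
    list(spacers = spacers, cores = cores, strands = strands, fill = fill,
         gene_assoc = runif(n) < cfg$gene_assoc_fraction,
         has_orth = runif(n) < cfg$ortholog_fraction,
         sharp = runif(n) < cfg$sharp_fraction,
         expr = stats::rlnorm(n, meanlog = 1, sdlog = 1))
  })

  # source contig assembly and coordinates
  src_core_start <- cumsum(c(0L, (src$spacers + core_len)[-n])) +
    src$spacers + 1L
  src_seq_parts <- character(2L * n + 1L)
  sp_seqs <- with_stream(cfg$seed, "source_spacers", 0L,
                         vapply(src$spacers, random_dna, character(1)))
  for (i in seq_len(n)) {
    src_seq_parts[2L * i - 1L] <- sp_seqs[i]
    src_seq_parts[2L * i] <- if (src$strands[i] == "-")
      revcomp_chr(src$cores[i]) else src$cores[i]
  }
  src_seq_parts[2L * n + 1L] <- src$fill
  source_contigs <- setNames(paste(src_seq_parts, collapse = ""), main)
  for (sc in scafs) {
    L <- cfg$contig_layout$length[cfg$contig_layout$name == sc]
    source_contigs[sc] <- with_stream(cfg$seed, "source_scaffold",
                                      match(sc, scafs), random_dna(L))
  }
  source_genome <- genome_sequence(source_contigs,
                                   contig_class = setNames(
                                     cfg$contig_layout$class,
                                     cfg$contig_layout$name))

  # source gene/promoter coordinates (core position 401 = TSS)
  core_pos <- function(o, strand, p) # core coordinate p -> contig position
    if (strand == "-") o + core_len - p else o + p - 1L
  src_tss <- mapply(function(o, s) core_pos(o, s, 401L), src_core_start,
                    src$strands)
  src_gene_start <- ifelse(src$strands == "+", src_tss,
                           src_tss - cfg$gene_len + 1L)
  source_genes <- gene_models(paste0("sg", seq_len(n)), main,
                              src_gene_start,
                              src_gene_start + cfg$gene_len - 1L,
                              src$strands)

  # target: mutate cores, insert repeats, duplicate some loci
  tgt <- with_stream(cfg$seed, "target", cfg$target_stream, {
    spacers <- sample(80:160, n, replace = TRUE)
    sp_seqs <- vapply(spacers, random_dna, character(1))
    mut <- lapply(src$cores, mutate_seq, sub_rate = cfg$promoter_divergence,
                  indel_rate = cfg$indel_rate)
    rep_here <- runif(n) < cfg$repeat_prob
    rep_info <- vector("list", n)
    for (i in which(rep_here)) {
      L <- sample(cfg$repeat_len_range[1L]:cfg$repeat_len_range[2L], 1L)
      motif <- sample(REPEAT_MOTIFS, 1L)
      rep_seq <- substr(strrep(motif, ceiling(L / nchar(motif))), 1L, L)
      # insert mid-window (after the image of core position ~250)
      at <- mut[[i]]$map[250L]
      at <- if (is.na(at)) 250L else at
      s <- mut[[i]]$seq
      mut[[i]]$seq <- paste0(substr(s, 1L, at), rep_seq,
                             substr(s, at + 1L, nchar(s)))
      mut[[i]]$map <- ifelse(mut[[i]]$map > at, mut[[i]]$map + L,
                             mut[[i]]$map)
      rep_info[[i]] <- c(at = at, len = L)
    }
    n_dup <- floor(cfg$duplication_fraction * n)
    dup_genes <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
    on_scaf <- if (n_dup > 0)
      runif(n_dup) < cfg$scaffold_copy_fraction else logical(0)
    if (!length(scafs)) on_scaf[] <- FALSE
    list(spacers = spacers, sp_seqs = sp_seqs, mut = mut,
         rep_here = rep_here, rep_info = rep_info, dup_genes = dup_genes,
         dup_on_scaf = on_scaf,
         fill_seed = sample.int(1e6, 1L))
  })

  tgt_core_len <- vapply(tgt$mut, function(m) nchar(m$seq), integer(1))
  tgt_core_start <- cumsum(c(0L, (tgt$spacers + tgt_core_len)[-n])) +
    tgt$spacers + 1L
  used <- sum(tgt$spacers) + sum(tgt_core_len)
  if (used > main_len)
    stop("contig layout too small for the mutated target loci")

  # verbatim duplicate copies: chromosomal copies go into the chr tail,
  # scaffold copies onto the first unplaced scaffold
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, tgt$sp_seqs[i],
               if (src$strands[i] == "-") revcomp_chr(tgt$mut[[i]]$seq)
               else tgt$mut[[i]]$seq)
  }
  tail_parts <- character(0)
  tail_pos <- used
  dup_copy <- data.frame(gene = integer(0), contig = character(0),
                         start = integer(0), end = integer(0))
  with_stream(cfg$seed, "target_fill", cfg$target_stream, {
    chr_dups <- tgt$dup_genes[!tgt$dup_on_scaf]
    for (g in chr_dups) {
      gap <- 100L
      seq_g <- if (src$strands[g] == "-") revcomp_chr(tgt$mut[[g]]$seq)
        else tgt$mut[[g]]$seq
      tail_parts <- c(tail_parts, random_dna(gap), seq_g)
      dup_copy <- rbind(dup_copy, data.frame(
        gene = g, contig = main, start = tail_pos + gap + 1L,
        end = tail_pos + gap + nchar(seq_g)))
      tail_pos <- tail_pos + gap + nchar(seq_g)
    }
    if (tail_pos > main_len)
      stop("contig layout too small for duplicated loci")
    tail_parts <- c(tail_parts, random_dna(main_len - tail_pos))
  })
  target_contigs <- setNames(paste(c(parts, tail_parts), collapse = ""),
                             main)

  with_stream(cfg$seed, "target_scaffold", cfg$target_stream, {
    for (sc in scafs) {
      L <- cfg$contig_layout$length[cfg$contig_layout$name == sc]
      pos <- 0L
      sparts <- character(0)
      if (sc == scafs[1L]) {
        for (k in which(tgt$dup_on_scaf)) {
          g <- tgt$dup_genes[k]
          gap <- 100L
          seq_g <- if (src$strands[g] == "-")
            revcomp_chr(tgt$mut[[g]]$seq) else tgt$mut[[g]]$seq
          if (pos + gap + nchar(seq_g) > L)
            stop("scaffold too small for duplicated copies")
          sparts <- c(sparts, random_dna(gap), seq_g)
          dup_copy <- rbind(dup_copy, data.frame(
            gene = g, contig = sc, start = pos + gap + 1L,
            end = pos + gap + nchar(seq_g)))
          pos <- pos + gap + nchar(seq_g)
        }
      }
      sparts <- c(sparts, random_dna(L - pos))
      target_contigs[sc] <- paste(sparts, collapse = "")
    }
  })

  # target coordinates: image of core coordinate p for gene i
  img <- function(i, p) {
    m <- tgt$mut[[i]]$map
    v <- m[p]
    if (is.na(v)) { # nearest kept neighbour
      kept <- which(!is.na(m))
      v <- m[kept[which.min(abs(kept - p))]]
    }
    o <- tgt_core_start[i]
    if (src$strands[i] == "-") o + tgt_core_len[i] - v else o + v - 1L
  }
  tgt_tss <- vapply(seq_len(n), function(i) img(i, 401L), numeric(1))
  w_lo <- vapply(seq_len(n), function(i) img(i, 1L), numeric(1))
  w_hi <- vapply(seq_len(n), function(i) img(i, 501L), numeric(1))
  t_win_start <- as.integer(pmin(w_lo, w_hi))
  t_win_end <- as.integer(pmax(w_lo, w_hi))
  g_lo <- vapply(seq_len(n), function(i) img(i, 401L), numeric(1))
  g_hi <- vapply(seq_len(n), function(i) img(i, 400L + cfg$gene_len),
                 numeric(1))
  target_genes <- gene_models(paste0("tg", seq_len(n)), main,
                              as.integer(pmin(g_lo, g_hi)),
                              as.integer(pmax(g_lo, g_hi)),
                              src$strands)

  # target mask: the inserted repeats
  mask <- GenomicRanges::GRanges()
  for (i in which(tgt$rep_here)) {
    at <- tgt$rep_info[[i]]["at"]; L <- tgt$rep_info[[i]]["len"]
    if (src$strands[i] == "-") {
      hi <- tgt_core_start[i] + tgt_core_len[i] - (at + 1L)
      lo <- hi - L + 1L
    } else {
      lo <- tgt_core_start[i] + at
      hi <- lo + L - 1L
    }
    mask <- c(mask, GenomicRanges::GRanges(main,
                                           IRanges::IRanges(lo, hi)))
  }
  target_genome <- genome_sequence(target_contigs, mask = mask,
                                   contig_class = setNames(
                                     cfg$contig_layout$class,
                                     cfg$contig_layout$name))

  gene_id <- ifelse(src$gene_assoc, paste0("sg", seq_len(n)),
                    NA_character_)
  in_table <- src$gene_assoc & src$has_orth
  orthologs <- ortholog_table(paste0("sg", which(in_table)),
                              paste0("tg", which(in_table)))
  promoters <- promoter_set(paste0("p", seq_len(n)), main, src_tss,
                            src$strands, gene_id = gene_id,
                            has_target_ortholog = in_table,
                            genome = source_genome)

  duplicated_flag <- seq_len(n) %in% tgt$dup_genes
  scaffold_copy <- seq_len(n) %in% tgt$dup_genes[tgt$dup_on_scaf]
  expected <- ifelse(promoters$excluded, "unmapped",
              ifelse(cfg$promoter_divergence >= 0.40, "unmapped",
              ifelse(in_table, "ortholog_mapped",
              ifelse(duplicated_flag & scaffold_copy, "rescued_scaffold",
              ifelse(duplicated_flag, "multimapped", "unique")))))
  truth <- data.frame(
    promoter_id = promoters$promoter_id, gene_id = gene_id,
    target_gene_id = paste0("tg", seq_len(n)),
    has_ortholog = in_table, anno_class = promoters$anno_class,
    duplicated = duplicated_flag, copy_on_scaffold = scaffold_copy,
    repeat_inserted = tgt$rep_here, expected_status = expected,
    t_contig = main, t_start = t_win_start, t_end = t_win_end,
    t_tss = as.integer(tgt_tss), strand = src$strands,
    tss_shape = ifelse(src$sharp, "sharp", "broad"), expr = src$expr,
    stringsAsFactors = FALSE)

  list(source_genome = source_genome, target_genome = target_genome,
       promoters = promoters, source_genes = source_genes,
       target_genes = target_genes, orthologs = orthologs, truth = truth,
       dup_copies = dup_copy, config = cfg)
}

#' Simulate a CAGE FASTQ from the truth table
#'
#' Tag 5' ends are drawn around each promoter's true target-genome TSS
#' (sharp promoters: point mass with a small jitter fraction; broad:
#' Gaussian spread), the insert is read off the target genome in the
#' gene orientation, and each read is assembled as
#' 5' prefix + insert + start of the 3' adapter (36 bp total) so the
#' trimming stage is exercised. A configured fraction of reads is random
#' sequence to exercise the unmapped path.
#'
#' @param sim output of [simulate_genome_pair()].
#' @param config `SimConfig` (defaults to the one inside `sim`).
#' @param depth number of reads (defaults to `config$cage_depth`).
#' @return named character vector of reads; attribute `truth_tss` gives
#'   the generating 5'-end position of each read (NA for unalignable
#'   reads).
#' @export
simulate_cage_fastq <- function(sim, config = sim$config,
                                depth = config$cage_depth) {
  cfg <- config
  truth <- sim$truth
  insert_len <- cfg$read_len - nchar(cfg$prefix_5p) - 3L
  adapter_bit <- substr(cfg$adapter_3p, 1L, 3L)
  lens <- contig_lengths(sim$target_genome)
  with_stream(cfg$seed, "cage", cfg$target_stream, {
    if (depth == 0L)
      return(structure(setNames(character(0), character(0)),
                       truth_tss = integer(0)))
    n_bad <- rbinom(1L, depth, cfg$cage_unalignable)
    n_good <- depth - n_bad
    pick <- sample.int(nrow(truth), n_good, replace = TRUE,
                       prob = truth$expr)
    tss <- truth$t_tss[pick]
    sharp <- truth$tss_shape[pick] == "sharp"
    off <- integer(n_good)
    jit <- sharp & runif(n_good) < cfg$cage_error
    off[jit] <- sample(c(-3L:-1L, 1L:3L), sum(jit), replace = TRUE)
    off[!sharp] <- as.integer(round(rnorm(sum(!sharp), 0, cfg$broad_sd)))
    minus <- truth$strand[pick] == "-"
    p5 <- tss + ifelse(minus, -off, off)
    contig <- truth$t_contig[pick]
    p5 <- pmin(pmax(p5, insert_len), lens[contig] - insert_len)
    start <- ifelse(minus, p5 - insert_len + 1L, p5)
    end <- start + insert_len - 1L
    inserts <- vapply(seq_len(n_good), function(i) {
      s <- genome_subseq(sim$target_genome, contig[i], start[i], end[i])
      if (minus[i]) revcomp_chr(s) else s
    }, character(1))
    bad <- vapply(seq_len(n_bad), function(i) random_dna(insert_len),
                  character(1))
    reads <- paste0(cfg$prefix_5p, c(inserts, bad), adapter_bit)
    names(reads) <- paste0("r", seq_len(depth))
    ord <- sample.int(depth)
    structure(reads[ord],
              truth_tss = c(p5, rep(NA_integer_, n_bad))[ord])
  })
}

#' Simulate aligned RNA-Seq fragments
#'
#' Fragment counts per gene are multinomial with probability proportional
#' to expression times exonic length; fragments are uniform within the
#' gene span. Fragments from duplicated loci are flagged multimapped
#' (their sequence occurs twice in the target genome).
#'
#' @param sim output of [simulate_genome_pair()].
#' @param config `SimConfig`.
#' @param depth number of fragments.
#' @return list: `fragments` (`GRanges` with gene-of-origin in `read_id`
#'   metadata) and `library_size`.
#' @export
simulate_rnaseq_fragments <- function(sim, config = sim$config,
                                      depth = config$rnaseq_depth) {
  cfg <- config
  genes <- sim$target_genes
  truth <- sim$truth
  with_stream(cfg$seed, "rnaseq", cfg$target_stream, {
    prob <- truth$expr * genes$exonic_length
    counts <- as.integer(rmultinom(1L, depth, prob))
    gidx <- rep.int(seq_along(genes), counts)
    gs <- GenomicRanges::start(genes)[gidx]
    ge <- GenomicRanges::end(genes)[gidx]
    span <- pmax(1L, ge - gs + 1L - cfg$frag_len + 1L)
    fs <- gs + floor(runif(length(gidx)) * span)
    fe <- pmin(ge, fs + cfg$frag_len - 1L)
    frags <- aligned_fragments(
      as.character(GenomicRanges::seqnames(genes))[gidx], fs, fe,
      read_id = paste0("f", seq_along(gidx)),
      multimapped = truth$duplicated[gidx])
    frags$gene_id <- genes$gene_id[gidx]
    list(fragments = frags, library_size = depth)
  })
}

#' Write a FASTA file from a GenomeSequence
#' @param genome `GenomeSequence`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Write reads as FASTQ (constant quality)
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  q <- strrep("I", nchar(reads))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", q), path)
  invisible(path)
}
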