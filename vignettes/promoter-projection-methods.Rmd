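---
title: "Cross-species promoter projection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species promoter projection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(promap)
```

## The model

`promap` treats a promoter as a fixed 501-bp genomic window around a
CAGE-defined transcription start site: 400 bases upstream and 100
downstream, TSS base included. The biological rationale is that sequence
conservation around mammalian TSS decays to background roughly beyond
−300/+100, and polymerase occupancy concentrates within ~500 bp of the
main TSS, so this window carries most of the alignable promoter signal
while staying short enough to place unambiguously.

Projection of such a window onto a second genome is a local-alignment
problem with two characteristic failure modes that the pipeline is built
around:

* **Repeat interruptions.** Proximal promoters are frequently interrupted
  by short repeat-element insertions in one lineage, which fragment the
  alignment and distort scores. The pipeline therefore searches a
  repeat-masked target genome and, more importantly, looks in the
  *orthologous upstream region first*: if the promoter's gene has known
  orthologs, the window is aligned only against their 2101-bp upstream
  windows (2 kb + 101 bases around the gene 5' end), where a weak but
  correctly located hit beats a strong hit elsewhere.
* **Assembly ambiguity.** Draft assemblies contain duplicated segments and
  unplaced scaffolds. A window with several placements is not discarded
  outright: it is *rescued* when the second-to-first bit-score ratio is
  below 0.95, or when exactly one placement lies on a chromosome and all
  others on unplaced scaffolds (assembly fragmentation, not genuine
  duplication, is then the parsimonious explanation).

Windows not mapped by the orthology pass go through two genome-wide
passes: a divergence-tolerant scheme (reward 1, penalty −1, gap opening
free, 2 per gap base, identity ≥ 20 %, e-value ≤ 0.01), then — for
windows still unmapped — a strict scheme (reward 1, penalty −3, gap open
3, extend 3; the identity and e-value cutoffs carry over). Multimapped
windows from the first genome-wide pass are final: only unmapped windows
are re-aligned, mirroring the two-iteration design the pipeline emulates.
Promoters that end multimapped or unmapped are "not reported"; everything
else carries exactly one placement.

## The alignment engine

The engine is a seeded local aligner: contiguous 11-mer seeds are looked
up in a k-mer index of the target, grouped by diagonal, and extended with
an affine-gap Smith–Waterman (Gotoh) over a bounded region, with full
traceback for identity computation. Eleven was chosen as the seed length
because it is also the pipeline's global minimum query length (the
iterative tag-trimming floor), so a single index serves every stage.

Two details matter for faithfulness:

* **Two-hit seeding.** A candidate region is extended only when two
  non-overlapping seeds support it on near-identical diagonals (≤ 16 bp
  of drift, covering plausible indel accumulation across a 501-bp
  window). A lone 11-mer match is never extended. This is the classic
  two-hit heuristic, and it is what gives the engine
  discontiguous-template-like specificity: without it, optimal extension
  of chance seeds yields weak spurious alignments that pass a 0.01
  e-value cutoff on desk-scale genomes, and random windows stop being
  rejected. Short CAGE tags are the deliberate exception (a 25-bp read
  cannot be asked for two distant seeds), so tag alignment runs in
  single-hit mode; its specificity comes instead from a raised identity
  floor and the soft-clip cap below.
* **Score statistics.** Bit-scores and e-values use the Karlin–Altschul
  forms `bit = (λS − ln K)/ln 2` and `E = K·m·n·e^{−λS}`, with
  `(λ, K) = (1.28, 0.46)` for the tolerant scheme and `(1.37, 0.71)` for
  the strict one — standard ungapped table values applied to gapped
  scores, as short-read aligners commonly do for these presets. Absolute
  bit-scores from any two engines differ; every *decision* in the
  pipeline that uses them is a ratio or a cutoff, which is what the
  constants must preserve. The constants are recorded in
  `scoring_scheme()` and overridable.

An exhaustive Smith–Waterman oracle (`sw_oracle()`) is part of the
package surface: it shares no code path with the seeded search beyond the
inner DP routine being verified against it, and the test suite sweeps
hundreds of randomized query/target pairs asserting the seeded top score
never exceeds the oracle and equals it whenever a confidently seeded hit
is reported.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| promoter window | −400/+100 | bp | alignable promoter signal around the TSS |
| ortholog window | 2000 + 101 | bp | orthology-first search space |
| score ratio | 0.95 | — | multimapper rescue threshold (`s2/s1`) |
| min tag length | 20 | bp | CAGE read filter after trimming |
| trim floor | 11 | bp | iterative-rescue stopping length |
| soft clip | 2 | bases/end | maximum unaligned tag termini |
| extension length | 501 | bp | tag/promoter extension before clustering |
| proximity | 100 / 2000 | bp | CTSS-promoter association cutoffs |
| coverage grid | 250 × 100 | windows × bp | −5 kb..+20 kb around midpoints |
| evidence windows | m−2..m+4 | windows | −200..+400 around the midpoint |
| evidence floor | 1 | FPKM | windowed expression threshold |
| heatmap filter | 11 | reads | row filter over the first 100 windows |

All of these sit in `run_config()` with the values above as defaults.

## Numerical and convention choices

* **Coordinates.** Internally everything is a `GRanges` (1-based closed),
  the canonical Bioconductor container; BED I/O converts to 0-based
  half-open at the file boundary. Human-readable reports are 1-based.
* **Midpoint.** For an even-length interval the midpoint is
  `start + floor(length/2)` in 0-based terms. The midpoint base falls in
  coverage-matrix column 51 (5000/100 upstream windows + 1); the matrix
  exposes this as an attribute rather than hard-coding it downstream.
* **Seven evidence windows.** Columns `m−2..m+4` are the only contiguous
  seven-window set covering 200 bp upstream through 400 bp downstream
  while containing the midpoint window; window-length (100 bp), not gene
  length, is the per-kilobase denominator for the windowed FPKM.
* **Extension split.** Extending an L-bp placement to 501 bp adds
  `501 − L` bases split floor/ceil with the extra base on the 5' side,
  strand-aware, clipped at contig edges.
* **Clustering.** CTSS clusters merge placements overlapping by ≥ 1 base
  per contig and strand; abutting intervals stay separate. Strandedness
  follows CTSS semantics in the CAGE literature even though tag clusters
  could be defined unstranded. Implementation is `reduce(min.gapwidth =
  0)`; an all-pairs O(n²) merge oracle checks it in the tests.
* **Proximity.** Distance between features is the gap between closest
  ends (0 for overlap), strand-agnostic; ties in nearest-feature lookups
  break to the leftmost feature start.
* **HSP merging.** Placements of one query within 50 bp on the same
  contig and strand are merged (best score kept) before uniqueness is
  judged, so alignment-engine fragmentation does not masquerade as
  multimapping.
* **Scaffold clause scope.** The rescue clause is applied whenever ≥ 2
  hits exist, not only in the literal two-hit case — the underlying cause
  (assembly fragmentation) is not specific to two hits. The literal
  behaviour is available via `scaffold_max_hits = 2`.
* **Orthology-pass uniqueness.** Hits within the ortholog-window set are
  never multimapped; the best bit-score wins, with ties broken by gene-id
  order. The orthology pass uses the same seeded engine as the
  genome-wide passes, so a homolog too diverged to seed is not silently
  accepted there either.
* **Tag rescue.** Only unmapped tags enter iterative trimming (each
  iteration removes one base from each end and realigns; stop at a single
  placement or when the next trim would go below 11 bp). Multimapped
  tags are not re-trimmed — trimming can only remove information, so it
  cannot disambiguate equal placements. Tags that become multimapped
  *during* trimming stop iterating and are reported multimapped.
* **Degenerate inputs.** Empty FASTA warns and yields an empty genome;
  promoter windows clipped below 250 bp are flagged and excluded from
  projection; a zero library size is an error rather than an NaN FPKM.

## What the generator emulates — and what it does not

`simulate_genome_pair()` builds a source genome of gene loci (400 bp of
promoter sequence, the TSS, a gene body) separated by random spacers,
then derives the target: each locus is copied and mutated at the
configured substitution and indel rates, intergenic sequence is drawn
independently (so background is unalignable), a configurable fraction of
loci is duplicated *verbatim* (some copies on an unplaced scaffold),
repeat motifs are inserted mid-window into a configurable fraction of
target promoters and recorded in the target mask, and a fraction of genes
receives a known ortholog. CAGE reads carry a fixed 8-bp 5' prefix and
the first bases of a 3' adapter inside 36-bp reads, with sharp
(point-mass, 2 % jitter) or broad (Gaussian, σ = 20 bp) TSS shapes and a
5 % unalignable fraction; RNA-Seq fragments are multinomial per gene with
probability ∝ expression × exonic length, uniform within the gene span.
Defaults (200 genes on a ~200-kb chromosome plus a 15-kb scaffold, 5 %
divergence, 0.2 % indels, 10 % repeat insertion, 5 % duplication, 80 %
orthology, 50 k tags, 100 k fragments) are the package's reference
conditions; a single master seed drives explicit per-component streams so
stages can be re-simulated independently, and a `target_stream` knob
yields two target species over one identical source.

Mutations are uniform per base — no transition/transversion bias, no CpG
effects, no indel length distribution beyond 1 bp — and repeats come from
a tiny planted motif library rather than real repeat families. Splicing
does not exist (exonic length = gene span), base qualities are constant,
and expression levels are i.i.d. log-normal. Passing the recovery tests
therefore demonstrates that the *decision logic* (windowing, rescue,
trimming, clustering, evidence) behaves correctly under controlled
divergence, duplication and noise; it does not establish sensitivity on
real genomes, where repeat structure, GC heterogeneity and assembly error
are far richer.

One measurement choice follows from the generator's design: promoters
whose target window received a simulated repeat insertion have no single
well-defined placement at 10-bp resolution (an aligner may legitimately
report either flank or span the insert), so the positional
parameter-recovery property conditions on the un-interrupted promoters.
Repeat-interrupted promoters are still simulated, projected and counted
in every status-level property.

## Problem sizes

The shipped test suite runs the oracle sweeps at 500 alignment pairs, 200
clustering sets and 5 × 100 nearest-feature queries, and the recovery
properties at the generator defaults above (plus a 60-locus full
duplication scenario and a 25-locus end-to-end determinism run). These
sizes were chosen to give the binomial properties enough resolution —
e.g. ~160 orthologous, non-duplicated promoters behind a ≥ 95 % recovery
bound — while keeping a full `R CMD check`-style run in single-digit
minutes on one core.

## Known limitations

* Absolute bit-scores and e-values are not comparable to other engines;
  only ratio/cutoff decisions are faithful.
* The scaffold-rescue clause depends on a correct chromosome/scaffold
  classification; with name-based classification (`scaffold_prefixes`),
  unusual contig naming schemes need an explicit `contig_class`.
* Enhancer windows can be projected as ordinary queries, but bidirectional
  eRNA detection is out of scope.
* The windowed evidence call uses all fragments including multimappers
  (deliberately, to capture duplicated gene families), so it is
  qualitative; per-gene FPKM, which excludes multimapped and ambiguous
  fragments, is the quantitative measure.
* CAGE normalization across libraries (tags-per-million) and differential
  expression are out of scope.
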