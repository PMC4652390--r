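Package: promap
Title: Cross-Species Projection of CAGE-Defined Promoters with Expression Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects CAGE-defined promoter windows from a source genome onto a
    target genome using an orthology-first, then genome-wide seeded local
    alignment strategy with explicit multimapper-rescue rules (bit-score ratio
    and chromosome-versus-scaffold tie-breaks). Projected promoter locations
    are corroborated by CAGE tag-cluster proximity and by windowed RNA-Seq
    coverage around the mapped promoter midpoints. Includes a synthetic-data
    generator that produces paired genomes, CAGE reads and RNA-Seq fragments
    with a full ground-truth table, so every stage of the pipeline can be
    exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
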