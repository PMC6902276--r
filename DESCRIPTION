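Package: zebralift
Title: Feature-Weighted Genome Alignment and Annotation Lift-Over
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-global pairwise genome alignment with per-feature-class
    ("zebraic") scoring that preferentially conserves coding sequence, splice
    sites and start/stop codons during genome-annotation lift-over. Includes
    open-reading-frame integrity checking, pseudo-genome construction from
    variant records with coordinate lift-over, projection of a reference
    annotation onto de novo assemblies, gene-anchored base-pair-resolution
    whole-genome variant calling with lossless genome reconstruction,
    per-feature multiple-sequence alignment for population variant
    uniformization, and a seeded synthetic-data generator for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    withr,
    ggplot2,
    generics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
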