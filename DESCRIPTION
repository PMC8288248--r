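Package: polyflor
Title: Gene-Family Expansion After Polyploidization for Flowering-Time Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying how flowering-time gene
    families expand and evolve after whole-genome duplication (WGD). Provides
    domain-architecture-based family identification with length and coverage
    filters, multiple-sequence-alignment conservation scoring and length-variation
    clustering, collinearity-based duplication classification (singleton,
    dispersed, proximal, tandem, WGD/segmental), microsynteny statistics around
    focal genes, reciprocal similarity networks, and Nei-Gojobori (1986)
    synonymous-distance estimation with Jukes-Cantor correction. A bundled
    simulator of polyploid genome evolution (WGD with fractionation, tandem,
    proximal and dispersed duplications, codon-level divergence with
    controllable synonymous distance, repeat proliferation) generates every
    input format together with planted ground truth, so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
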