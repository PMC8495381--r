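Package: nettrace
Title: Single-Cell Tumor Evolution Analysis for Multi-Site Neuroendocrine Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying malignant progression across
    primary and metastatic tumor sites from single-cell RNA-seq data:
    expression-based copy-number profiling with quadrant classification of
    malignant cells, graph-based clustering and marker detection, k-nearest
    neighbor pseudotime with temporal trend-pattern mining, mitochondrial
    allele-frequency lineage trees with site-normalized clade composition and
    dominant-clone selection, derivation of a metastasis-associated gene
    signature, and Kaplan-Meier validation of marker combinations against
    disease-free survival. Includes a synthetic-data generator that plants
    every structure the analysis assumes (clonal copy-number events,
    heteroplasmic mitochondrial lineages, temporal expression programs,
    prognostic double-marker effects) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ape,
    broom,
    cluster,
    dplyr,
    ggplot2,
    igraph,
    methods,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
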