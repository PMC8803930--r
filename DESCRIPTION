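Package: regenconverge
Title: Cross-Species Metabolomic and Transcriptomic Convergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for identifying metabolites that
    converge with regenerative capacity across phylogenetically distant
    models. Implements untargeted-metabolomics normalization (minimum
    imputation, median rescaling, auto-scaling), differential metabolite
    (DPMP) and gene (DEG) calling with Benjamini-Hochberg correction,
    pathway-level differential-abundance (DA) and differential-expression
    (DE) scores, joint gene-metabolite over-representation, cross-model
    convergence tables with at-least-k-model candidate selection,
    rescue-DEG construction from injury and treatment contrasts,
    replicate-permutation Pearson correlation, PLS-DA ordination,
    model-similarity dendrograms, and phenotypic metabolite-screen
    ranking. Ships a synthetic-data generator with planted ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
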