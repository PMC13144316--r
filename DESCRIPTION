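Package: stratomics
Title: Race-Stratified Multi-Omics Comparison of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two tumor cohorts of unequal size across somatic
    mutations, copy-number variation, gene expression, and mutational
    signatures. Implements gene-level mutation frequency testing with
    Fisher's exact test and Benjamini-Hochberg FDR control plus bootstrap
    odds-ratio stability; segment-to-gene copy-number status assignment
    with conflict invalidation, chromosome-arm aggregation and per-sample
    burden comparison; rank-based cross-platform differential expression;
    SBS96 mutational-signature extraction by non-negative matrix
    factorization with stability-based model selection and reference
    decomposition; hypergeometric over-representation analysis and an
    integrative multi-layer enrichment matrix. Ships a synthetic two-cohort
    study generator with a ground-truth ledger for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Biostrings,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
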