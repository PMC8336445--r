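Package: horinfer
Title: Monomer and Higher-Order Repeat Inference for Satellite DNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation of satellite tandem-repeat arrays such as human
    alpha-satellite centromeres. Starting from an array sequence and a single
    consensus repeat unit, horinfer iteratively infers the minimal monomer
    alphabet that resolves the array, translates the array into a string over
    that alphabet, and infers higher-order repeats (HORs), superHORs and the
    HOR-graph by greedy grammar-style substring substitution under a
    run-length-encoding objective. Includes hybrid-monomer detection,
    monomer-set shifting, a nested-tandem-repeat simulator with ground truth,
    and readers/writers for FASTA, TSV, BED and DOT outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    optparse,
    utils,
    stats,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
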