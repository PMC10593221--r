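Package: clonegrower
Title: Clonal Tree Inference from Ultra-Low Coverage Single-Cell DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a clonal tree, clonal single-nucleotide variant (SNV)
    genotypes, and a cell clustering with maximum posterior probability from
    ultra-low coverage single-cell DNA sequencing data. The tree is grown
    recursively from a single root by elementary operations (Linear, Branching,
    Identity) that fuse copy-number signal, carried by a low-dimensional
    embedding of binned read counts, with sparse variant read counts via a
    combined feature and a normalized-cut cell bipartition. Includes a matched
    simulator of clonal trees, copy-number profiles and read counts at
    0.01-0.1x coverage, pair-recall evaluation metrics (APR/IPR/CPR and
    weighted accuracy for cells and SNVs), genotype similarity, cell
    mutational burden diagnostics, and a pooled-read baseline genotyper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    Rcpp,
    generics,
    withr,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    mclust,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
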