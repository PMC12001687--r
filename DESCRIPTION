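Package: glp
Title: Highly Variable Gene Selection by BIC-Tuned Robust LOESS on the
    Positive Ratio
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects informative (highly variable) genes from single-cell
    RNA-seq count matrices by modelling the relationship between each
    gene's positive ratio (fraction of cells with a nonzero count) and its
    mean expression with a two-round robust LOESS regression whose span is
    chosen by the Bayesian Information Criterion.  Genes whose mean
    expression lies well above the level predicted from their positive
    ratio receive high windowed residual Z-scores and are ranked as
    candidate features for downstream analysis.  Includes readers for
    10x-style Matrix Market and dense delimited count matrices, a
    Poisson-based synthetic-data generator with ground-truth marker
    genes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
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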