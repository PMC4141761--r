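Package: wmaxc
Title: Condition-Specific Sub-Network Identification by Weighted Maximum
    Clique Relaxation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies a single condition-specific sub-network from
    two-condition gene-expression data, optionally integrated with a
    protein-protein interaction network. Genes are scored with a moderated
    two-sample T-statistic, gene pairs with the expectation of a
    conditional T-statistic over the two-condition mixture, and PPI pairs
    with a distance-based T-score. The scores define a weighted background
    network whose densest, most differential part is found by maximizing a
    quadratic form over the standard simplex (a Motzkin-Straus maximum
    clique relaxation) with a continuous genetic algorithm followed by
    exact Euclidean projection onto the simplex. A simulation module
    generates planted-module multivariate-normal studies and evaluation
    metrics so the whole pipeline can be benchmarked without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
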