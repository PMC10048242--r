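Package: narnea
Title: Maximum-Entropy Gene Set Analysis and Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric analytical-rank-based enrichment analysis (NaRnEA)
    for weighted gene sets, with a fully analytical null model derived from the
    Principle of Maximum Entropy. Computes directed and undirected enrichment
    scores over a rank/sign-transformed differential gene expression signature,
    combines them into a standard-normal Normalized Enrichment Score with
    analytical p-values, and reports a bounded Proportional Enrichment Score
    effect size together with leading-edge analysis. Includes an
    ARACNe3-style engine that reverse-engineers regulon gene sets from
    expression profiles by adaptive-partitioning mutual information with a
    piecewise empirical/robust-tail null model, FDR pruning, data-processing
    inequality pruning and consensus integration; synthetic-data generators;
    and calibration and contingency-table validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
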