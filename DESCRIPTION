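Package: noa
Title: Network Outcome Analysis for Symptom Networks with a Binary Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates mixed graphical models over ordinal symptom items and a
    binary treatment outcome by nodewise L1-regularized (LASSO) regression with
    cross-validated penalty selection, so that edges adjacent to the outcome
    node identify symptoms that uniquely and directly predict the outcome while
    conditioning on all other symptoms (Network Outcome Analysis). Includes
    bootstrap edge-stability analysis, moderated network models for testing
    whether a binary grouping variable changes any pairwise relation,
    translation of outcome-adjacent edge weights into per-point and cumulative
    odds ratios, baseline-table summary statistics (Yates-corrected chi-square,
    Welch t), a Gibbs-sampler cohort simulator with known ground-truth network
    structure, and network export to edge-list JSON and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
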