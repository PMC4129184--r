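Package: pltreg
Title: Partially Linear Tree-Based Regression with Confounder Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits partially linear tree-based regression (PLTR) models for a
    binary outcome: a generalized linear confounder part combined with a
    recursive-partitioning part over explanatory variables, estimated by an
    iterative offset scheme.  Provides forward construction of nested subtree
    sequences, tree-size selection by BIC, AIC or K-fold cross-validation, and
    a generalized likelihood-ratio test whose scaled chi-squared null law is
    calibrated by a conditional parametric bootstrap.  Includes simulation
    generators for benchmark scenarios with independent and hierarchically
    dependent binary predictors, a replicate-level experiment harness, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
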