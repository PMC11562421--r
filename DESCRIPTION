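Package: panelnets
Title: Panel Network Models for Adolescent Internalizing and Externalizing
    Symptom Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of panel network models for few-wave longitudinal
    cohort data on continuous symptom scales: cross-lagged panel networks
    (node-wise LASSO regressions with 10-fold cross-validated penalty
    selection), cross-sectional Gaussian graphical models selected by the
    extended Bayesian information criterion along a graphical-lasso path,
    and panel graphical vector autoregression with random intercepts
    separating within-person temporal/contemporaneous networks from the
    between-person network, fitted by full-information maximum likelihood
    under missingness, pruned with Wald tests and a score-test step-up
    search, and evaluated with chi-square based fit indices. Includes
    in-/out-strength and bridge centrality, case-dropping bootstrap
    stability analysis, executive-functioning score derivation with outlier
    screening, hierarchical FIML regressions, a synthetic cohort generator
    emulating a three-wave adolescent panel design, and a config-driven
    pipeline that reproduces the full analysis graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
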