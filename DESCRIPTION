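Package: psdrsim
Title: Propensity and Disease Risk Score Matching Evaluated by Plasmode
    Simulation and Negative Control Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate machine-learning estimation of propensity
    scores (PS) and disease risk scores (DRS) for confounding adjustment in
    pharmacoepidemiology. Provides a synthetic base-cohort generator
    (sparse correlated binary covariates, prescription records, rare
    covariate-driven outcomes, negative-control time-to-event outcomes with
    a true hazard ratio of one), drug-era construction with a refill-gap
    rule, a plasmode simulation engine that resamples observed covariates
    and injects a known treatment effect, four score-estimation methods
    (reference logistic regression, L1-penalised logistic regression,
    gradient-boosted trees, multi-layer perceptron) tuned by 10-fold
    cross-validated Brier score, greedy variable-ratio caliper matching,
    covariate balance diagnostics (standardised mean differences), matched
    Cox and logistic effect estimation, and aggregation into coverage,
    RMSE and relative-bias reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    glmnet,
    Matrix,
    xgboost,
    nnet,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
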