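Package: inrcast
Title: Warfarin Dose Decision Support via Sequential PT INR Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for individualized warfarin dosing support. Implements a
    5th-day prothrombin time international normalized ratio (PT INR) predictor
    that combines a dense branch over static patient covariates (sex, age,
    weight, height, body surface area) with a stacked LSTM branch over four
    days of (PT INR, warfarin dose) pairs; an autoregressive chain calculator
    that rolls the predictor forward under virtual fixed daily doses to emit
    individualized dose-INR tables for days 5-8; accuracy-band evaluation and
    two-proportion comparison statistics; and a pharmacokinetic-pharmacodynamic
    inpatient cohort simulator that generates titration-style dosing records
    with delayed, dose-proportional INR responses for training and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
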