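Package: gaitffdb
Title: Staged Factorial Benchmark for Neural-Network Regression on Gait Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transparent, recoverable hyperparameter optimization of
    deep feed-forward regressors that predict 2-minute-walk-test distance from
    aggregated wearable-sensor gait features. Implements a staged fractional
    factorial design benchmark (epoch calibration, learning-rate sweep, model
    shape grid, algorithm comparison) over seven first-order training
    algorithms, scored by a relative rooted-mean-square-error metric with
    repeated seeded experiments; a reverse-synapse-weight feature-impact
    sanity check; intraclass-correlation reliability analysis; and a seeded
    synthetic gait-cohort generator so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
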