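Package: tvmttinar
Title: Time-Varying Mixture-Thinning Threshold INAR(1) Models for Count
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and inference for first-order threshold
    integer-valued autoregressive processes whose thinning probabilities
    vary over time through a logistic link in observable explanatory
    variables, with binomial thinning in one regime and negative-binomial
    thinning in the other (TVMTTINAR(1)). Provides exact transition
    probabilities, conditional least squares and conditional maximum
    likelihood estimation with asymptotic covariance estimators, two-step
    grid search for the integer threshold, Wald and likelihood-ratio
    tests for the piecewise structure and for the presence of explanatory
    variables, Pearson-residual diagnostics, and a seeded Monte Carlo
    harness reproducing the reference simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
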