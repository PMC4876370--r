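Package: mlar1sim
Title: Simulation Study of Estimation Procedures for Multilevel AR(1) Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Monte-Carlo comparison of estimators of the
    autocorrelation in two-level first-order autoregressive models for
    intensive longitudinal data. Provides a seeded generator of multilevel
    AR(1) panels with normally distributed individual autocorrelations
    truncated to the stationary region; four estimators of the population
    autocorrelation (per-individual exact maximum likelihood and its
    fixed-model aggregation, a restricted-maximum-likelihood
    random-intercept/random-slope fit, and fixed and hierarchical Bayesian
    models sampled by Markov chain Monte Carlo under Berger's symmetrized
    reference prior); the outcome measures of estimator quality (bias,
    empirical standard deviation, bias of the standard error, empirical
    rejection rate, percentile interval estimates, and tallies of
    non-convergence and non-stationary predictions); and a deterministic
    study runner over the fully crossed simulation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    yaml
Config/testthat/edition: 3
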