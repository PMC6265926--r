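Package: geoadditive
Title: Bayesian Geo-Additive Binary Regression for Spatial Survey Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian geo-additive binary regression models to
    record-level survey data: a Bernoulli-logit likelihood with parametric
    fixed effects, second-order random-walk (RW2) smooth effects of
    continuous covariates, and intrinsic conditional autoregressive (ICAR)
    district-level spatial effects.  Posterior sampling uses exact
    Polya-Gamma data augmentation (Gibbs), model comparison uses the
    deviance information criterion (DIC), and a synthetic survey generator
    with known nonlinear and spatial truth supports end-to-end validation.
    Includes the descriptive prevalence and chi-square screening stage that
    typically precedes such multivariate analyses, adjacency-graph
    utilities, and choropleth-style plotting of posterior spatial effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    readr,
    jsonlite,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
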