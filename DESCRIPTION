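Package: nutricate
Title: Heterogeneous Treatment Effects of Maternal Education on Severe
    Child Undernutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating heterogeneous (conditional
    average) treatment effects of maternal education on severe child
    undernutrition in conflict-affected settings. Implements WHO-style LMS
    growth z-scores and the Bristol any-indicator rule for the severe
    undernutrition outcome, kernel-density conflict-intensity surfaces with
    retrospective exposure windows, a survey-constrained Voronoi-merge
    spatial partition, a from-scratch probit Bayesian Additive Regression
    Trees (BART) sampler with latent-variable augmentation, counterfactual
    CATE estimation with bootstrap credible regions, classifier diagnostics,
    and a synthetic DHS-like data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    withr,
    stats,
    utils,
    Rcpp,
    ggplot2,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
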