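Package: gngbias
Title: Pavlovian Bias in the Orthogonalized Go-NoGo Task: Models, Hierarchical
    Fitting and Longitudinal Psychometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reinforcement-learning models of Pavlovian bias in the
    orthogonalized Go-NoGo task (valenced-learning, valenced-sensitivity,
    sensitivity-ratio and forgetting variants), fitted hierarchically by
    type-2 maximum-likelihood expectation-maximization with integrated
    likelihoods and the integrated Bayesian Information Criterion.  Includes
    out-of-sample model comparison by left-out likelihoods with audits of
    informed versus agnostic handling of held-out trials, model-free
    descriptive indices of Pavlovian bias, test-retest statistics, latent
    change score models, Gaussian-mixture clustering of model fit, and a
    synthetic-cohort generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
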