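Package: attributr
Title: Grid-Based Bayesian Modelling of Intentional Attributions in the
    Iterated Dictator Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a discretized joint Bayesian belief model of
    intentional attributions (harmful intent and self-interest) during an
    iterated Dictator game, together with hierarchical random-effects
    fitting and comparison of three model variants via Laplace-approximated
    evidence, a seeded synthetic-cohort generator, and downstream analyses:
    Bayesian paired parameter contrasts, attribution precision and its
    regression on likelihood weights, trial-wise attributional coupling,
    and exploratory factor analysis with cross-validated drug
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    readr,
    jsonlite,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
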