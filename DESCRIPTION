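Package: jolcross
Title: Cross-Agent Prediction of Recognition Memory from Judgments of
    Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether an agent's per-item judgments of
    learning (JOLs) predict human recognition memory. Implements a
    counterbalanced within-subject study design for garden-path sentence
    materials, a synthetic-data generator for human cohorts and stochastic
    large-language-model raters, crossed random-intercept mixed models
    (binomial and Gaussian) with type-2 Wald tests, a structured cluster
    bootstrap of JOL-accuracy slopes with percentile confidence intervals
    and a permutation-null diagnostic, and an exact noncentral-t a-priori
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
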