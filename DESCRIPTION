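Package: radsmmi
Title: Radiation Attributed Decrease of Survival with Multi-Method
    Multi-Model Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Radiation Attributed Decrease of Survival (RADS)
    for all-solid-cancer incidence from excess relative and absolute risk
    models of the Life Span Study family, with model averaging across
    candidate dose-response models using information-criterion (AIC/BIC)
    weights, Monte Carlo propagation of coefficient and baseline-rate
    uncertainty, and a multi-method-multi-model inference (M4I) combiner
    that merges the four method-level estimates (AIC/BIC crossed with
    original/same baseline) into one general risk estimate per mission
    scenario with Gaussian error propagation. Includes a synthetic-data
    generator for model registries, baseline incidence tables and mission
    scenarios so the full pipeline is testable without access to fitted
    coefficient sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
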