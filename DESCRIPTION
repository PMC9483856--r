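Package: genopred
Title: Multi-Trait Genomic Prediction with Partial Least Squares and Bayesian GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-environment, multi-trait genomic prediction for plant
    breeding. Implements a multi-response partial least squares (MT-PLS)
    regression on kernel-augmented predictors built from the VanRaden genomic
    relationship matrix and an environmental-covariate kernel, a Bayesian
    multi-trait GBLUP benchmark fitted by Gibbs sampling, a deterministic
    mixed-model-equations solver, leave-one-environment-out cross-validation
    with nested component tuning, NRMSE and relative-efficiency reporting,
    and a synthetic-data generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
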