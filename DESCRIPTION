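Package: sorbkd
Title: QSPR Modelling of Pharmaceutical Sorption to Sewage Sludge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the sludge/water partition coefficient (Kd)
    of pharmaceuticals from molecular descriptors. Implements the full
    quantitative structure-property relationship (QSPR) workflow: descriptor
    reduction by coefficient-of-variation filtering and unsupervised forward
    selection, univariate and stepwise regression with leverage diagnostics,
    NIPALS partial least squares with leave-one-out component selection, and
    Bayesian-regularised neural network committees trained under the evidence
    framework with automatic relevance determination. A synthetic-data
    generator reproduces the statistical structure of literature Kd
    compilations (charge classes, replicate spread, correlated descriptor
    blocks) so every stage has a ground-truth test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
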