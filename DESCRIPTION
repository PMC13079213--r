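Package: psygxe
Title: Gene-Environment Interaction Analysis of Polygenic Risk and Childhood Adversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying joint and interactive effects of
    polygenic risk scores (PRS) and adverse childhood experiences (ACEs) on
    binary psychopathological phenotypes. Provides derivation of the binary
    ACE exposure from the five-item Childhood Trauma Screener, aggregation of
    multi-threshold polygenic scores by the standardized first principal
    component (PRS-PCA) with 75th-percentile dichotomization,
    Bonferroni-screened univariate and joint logistic regression models, and
    estimation of additive interaction (relative excess risk due to
    interaction, RERI, with delta-method confidence intervals) and
    multiplicative interaction (product-term log-odds coefficients). Includes
    a synthetic cohort generator with effects planted on either interaction
    scale, so every downstream estimate can be checked against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
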