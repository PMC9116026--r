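Package: missenseRisk
Title: Burden and Mixture Models for Breast Cancer Risk of Rare Missense Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Case-control analysis of rare missense variants in breast cancer
    susceptibility gene panels. Builds per-gene risk categories from protein
    domain membership and in silico deleteriousness scores, estimates
    stratified logistic regression burden odds ratios, and fits mixture
    models in which only a proportion (alpha) of the variants in each
    category is risk-associated, using an expectation-maximization algorithm
    with a weighted logistic maximization step. Includes training/validation
    calibration with fixed effect sizes, posterior-probability-weighted
    predicted odds ratios, a composite multi-gene model, familial
    relative-risk decomposition, and a synthetic cohort generator that
    reproduces the statistical structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
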