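Package: mmdti
Title: Multi-State Markov Modelling of Alzheimer's Progression with
    Tract-Profile Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A continuous-time three-state Markov model of Alzheimer's
    disease progression (normal cognition, amnestic mild cognitive
    impairment, Alzheimer's disease) with covariate-dependent transition
    intensities, fitted by maximum likelihood to interval-censored panel
    data via matrix-exponential transition probabilities.  Companion
    tools cover pointwise group comparison of automated-fiber-
    quantification tract profiles (classic, Welch and Brown-Forsythe
    one-way tests with age/sex adjustment and post hoc t-tests),
    confusion-matrix and ROC evaluation of multimodal classifiers, a
    seeded synthetic-cohort generator, and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    glmnet,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
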