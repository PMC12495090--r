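Package: bodyci
Title: Bayesian Causal Inference Modelling of Body Ownership and Metric
    Body Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for computational studies of body perception in aging:
    a Bayesian causal-inference observer model of visuo-proprioceptive
    integration, simulators for the visuo-proprioceptive disparity (VPD)
    reaching task and its companion unisensory protocols (proprioceptive
    judgment, open-loop reaching, midline judgment, two-point
    discrimination staircases), simulation-based maximum-likelihood
    fitting of per-participant sensory noise and common-cause prior,
    perceived limb-dimension indices from body-landmark localization,
    Lasso-based predictor selection for arm-length misperception, and a
    synthetic two-group cohort generator that emulates the statistical
    structure of an aging study so the full pipeline can be exercised and
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
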