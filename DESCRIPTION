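Package: hetefx
Title: Heterogeneous Treatment Effect Discovery via Parametric G-Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transparent, parametric, data-adaptive pipeline for detecting
    heterogeneous treatment effects in observational cohorts. Fits a penalized
    (LASSO/ridge/elastic-net) outcome model with treatment interactions on a
    training split, predicts both potential outcomes for every test-set
    individual by recycled predictions (G-computation), clusters the resulting
    conditional average treatment effects with Ward's method and a Beale-index
    rule for the number of clusters, flags effect modifiers by a cluster
    z-score variable importance with a data-derived cut-off for continuous
    modifiers, and reports subgroup effects on additive (risk difference) and
    relative (risk ratio) scales from a marginal structural model with
    inverse-probability-of-treatment weighting and robust or bootstrap
    inference. Includes a synthetic observational-cohort generator with known
    heterogeneous effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    sandwich,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
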