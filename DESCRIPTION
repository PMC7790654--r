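Package: ppmrange
Title: Presence-Only Point Process Distribution Models, Niche Analysis and
    Range Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for presence-only species distribution modelling in a
    point-process framework: spatial thinning of occurrence records,
    collinearity-based predictor selection (stepwise VIF and pairwise
    Spearman), penalized inhomogeneous-Poisson-process (maxent-equivalent)
    model fitting with AICc tuning over regularization multipliers and
    feature classes, threshold-based binary range maps and spherical
    range-size arithmetic, Ecological Niche Factor Analysis (marginality
    and specialization), model evaluation (AUC, omission rates, bootstrap
    partial ROC, Continuous Boyce Index), multi-period projection with
    niche-overlap and climate-stability mapping, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
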