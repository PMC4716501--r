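Package: pothresh
Title: Threshold Selection and Prevalence Estimation for Presence-Only
    Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for comparing threshold selection methods
    for presence-only species distribution models. Generates virtual species
    on a synthetic standardized landscape, fits DOMAIN, logistic regression,
    a penalized Maxent-like model, and Random Forest, selects binarization
    thresholds by maximizing the sum of sensitivity and specificity (maxSSS),
    the F measure (maxF), or its presence-background surrogate (maxFpb), and
    evaluates sensitivity, specificity, true skill statistic, F, AUC and
    threshold-based prevalence estimates across datasets with varying ratios
    of known presences to random background points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    randomForest,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
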