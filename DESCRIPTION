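Package: gestwin
Title: Critical Windows of Prenatal Air Pollution Exposure for Placental
    Epigenetic Gestational Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested analysis pipeline linking weekly prenatal ambient air
    pollution exposure to epigenetic gestational age acceleration or
    deceleration measured in placenta at birth. Provides inverse
    distance-squared interpolation of station-based pollutant measurements
    to maternal residences on a unified preconception-plus-pregnancy weekly
    axis, methylation-array quality control with empirical Bayes batch
    adjustment and gold-standard quantile normalization, reference-based
    placental cell-type deconvolution by constrained projection, linear
    epigenetic gestational age clocks with intrinsic and extrinsic
    age-acceleration residuals, period-average multivariable regression
    models, and weekly polynomial or natural-cubic-spline distributed lag
    models with AIC basis selection and critical-window extraction. A
    synthetic cohort generator with a full ground-truth record makes every
    stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    quadprog,
    geosphere,
    splines
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
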