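Package: maternomorph
Title: Statistical Prediction and Morph-Target Synthesis of Pregnant and
    Postpartum Body Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts body circumferences (chest, waist, hip, upper arm,
    thigh) and leg length of pregnant and postpartum women from simple
    covariates (age, height, pre-pregnancy weight, gravida, gestational or
    postpartum week) using published fixed-coefficient multiple linear
    regressions, models gestational weight gain and postpartum weight
    retention from the pre-pregnancy BMI category, and synthesizes a 3D body
    mesh by blending a bundled set of seven topology-identical synthetic
    avatars with BMI- and week-calibrated morph weights. Includes mesh
    cross-section girth measurement, re-calibration of the morph-correction
    tensor against any avatar set, ordinary-least-squares re-fitting of the
    measurement regressions from cohort data, method-agreement statistics,
    and a seeded synthetic longitudinal cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
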