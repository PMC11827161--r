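Package: apotraj
Title: Life-Course Cardiometabolic Trajectories by Adverse Pregnancy Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating life-course trajectories of repeated
    cardiometabolic measurements (blood pressure, BMI, cholesterol, glucose)
    in women grouped by adverse pregnancy outcome (APO) history. Derives
    woman-level APO exposure groups and comparator masks from a pregnancy
    register, fits fractional-polynomial random-intercept multilevel models
    with three-way polynomial-by-exposure-by-period interactions, and predicts
    group-specific mean trajectories with Wald confidence intervals. Includes
    a calibrated synthetic electronic-health-record cohort generator with
    known ground-truth curves for parameter-recovery validation, and a small
    command-line pipeline (simulate / fit / report).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
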