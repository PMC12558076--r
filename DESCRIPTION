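Package: lesionkinetics
Title: Ellipsoid Lesion Volumetry and Tumor Growth Rate Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing serial volumetric tumor measurements in
    clinical cohorts. Converts tri-planar lesion diameters into ellipsoid
    volumes, estimates per-patient exponential growth constants and the tumor
    growth rate (TGR, percent volume change per month), classifies volumetric
    progression, and reproduces the downstream cohort statistics used in
    observational growth-kinetics studies: median/IQR summaries, Mann-Whitney
    and Fisher exact group comparisons, Kaplan-Meier time-to-event curves with
    Greenwood variances, and a logistic progression model with listwise
    deletion. Includes a seeded synthetic-cohort generator so every pipeline
    stage is testable without patient-level data, plus CSV I/O, validation and
    a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
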