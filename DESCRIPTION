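Package: perimort
Title: Quality Assessment and Adjustment of Survey-Based Perinatal Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating stillbirth, early neonatal, and perinatal
    mortality from household-survey pregnancy data of at least seven months'
    gestation. Implements real-cohort interval-censored life tables over the
    stillbirth interval and single days of life up to day 9, four data-quality
    indicators (day-7 age-heaping index and three count ratios) classified
    against reference plausibility bands, and a family of adjustment models
    based on a modified Gompertz-Makeham hazard: smoothing of age-at-death
    heaping, a constrained stillbirth-to-very-early-neonatal hazard ratio for
    omission and transference, and upweighting of under-reported deaths on
    days 0-1. A synthetic cohort generator with a reporting-error injection
    taxonomy supports parameter-recovery experiments, and a command-line
    interface drives single-survey and multi-survey workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
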