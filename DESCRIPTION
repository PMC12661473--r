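Package: lnyield
Title: Prognostic Evaluation of Lymph Node Yield in Oral Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for asking whether lymph node yield (LNY) adds
    prognostic accuracy for 3- and 5-year mortality in oral squamous cell
    carcinoma. Provides inverse-probability-of-censoring-weighted (IPCW)
    binomial risk models, censoring-adjusted time-dependent ROC/AUC with
    cross-cohort external validation, G-computation population-average
    treatment effects over LNY ranges, a multivariable linear model of LNY
    determinants, random-effects meta-analysis with funnel-plot asymmetry
    diagnostics, and a reproducible multi-center synthetic cohort generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    sandwich,
    withr
Config/testthat/edition: 3
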