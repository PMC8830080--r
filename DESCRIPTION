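Package: staplercma
Title: Cost-Minimization Analysis of Powered Versus Manual Surgical
    Staplers in VATS Lobectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for hospital cost-minimization analysis (CMA) of
    powered versus manual endoscopic staplers in video-assisted
    thoracoscopic (VATS) lobectomy for lung cancer.  Provides a synthetic
    patient-cohort generator with known ground truth, eligibility
    filtering and descriptive group comparisons, gamma log-link
    generalized linear regression of per-category hospital costs with
    univariable screening, and a two-scenario decision model with device
    acquisition costs, one-way (tornado) sensitivity analysis, and Monte
    Carlo probabilistic sensitivity analysis.  Ships reference
    coefficient tables, device price lists, and baseline cost
    calibrations from a retrospective cost study of 388 VATS lobectomy
    episodes in a Chinese tertiary hospital, so the decision model can be
    run in an aggregate-calibrated mode without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
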