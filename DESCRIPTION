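Package: pdacrisk
Title: Pancreatic Cancer Risk Modeling in Diabetes Patients with Worsening
    Glycemic Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and validates risk-prediction models for pancreatic ductal
    adenocarcinoma (PDAC) among diabetes patients whose glycemic control is
    worsening. Provides a synthetic electronic-medical-record generator with
    known ground truth; construction of three overlapping progression cohorts
    (insulin initiation, combination oral hypoglycemic initiation, and a >=1
    percent HbA1c rise to >=8 percent); Cox proportional hazards models in
    which binary predictors carry log hazard ratios that decay exponentially
    with time since first diagnosis or prescription, fitted by iterative
    linearization; stepwise AIC model selection with duration-term
    constraints; internal validation via cumulative/dynamic time-dependent
    AUC, calibration slope, bootstrap optimism correction, and risk-threshold
    operating characteristics with exact confidence intervals; and
    age-standardized cumulative incidence with reverse Kaplan-Meier follow-up
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
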