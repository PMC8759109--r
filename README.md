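# pdacrisk

Risk-prediction modeling for pancreatic ductal adenocarcinoma (PDAC) among
diabetes patients whose glycemic control is worsening.

New-onset diabetes is a known PDAC signal, but *progression* of existing
diabetes — starting insulin, escalating from one oral hypoglycemic drug to
a combination, or an HbA1c jump of ≥ 1 percentage point to ≥ 8% — marks a
clinically actionable moment at which risk can be assessed. `pdacrisk`
implements that analysis as a tested, reusable pipeline on EMR-shaped
relational tables:

* **Synthetic EMR generator** (`sim_config()`, `generate_population()`):
  patients, diagnoses, prescriptions, labs, vitals and outcomes tables
  with known ground truth (cohort membership, index dates, true effects,
  true linear predictor), so every downstream stage is testable without
  any restricted data.
* **Cohort construction** (`identify_diabetes()`,
  `build_progression_cohorts()`, `extract_covariates()`,
  `exclude_incomplete()`): the diabetes base population (two outpatient
  diagnoses + qualifying outpatient lab, age ≥ 50), three overlapping
  progression cohorts with index dates and a 90-day early-progression
  exclusion, covariates from a 12-month proximal window with
  3-to-15-month change windows, and plausibility-filtered vitals.
* **Cox models with decaying effects** (`fit_linear_cox()`,
  `fit_decay_cox()`, `hr_at_lag()`, `schoenfeld_ph_test()`): a binary
  predictor recorded `t` months before cohort entry contributes
  `log HR(t) = beta1 * exp(-beta2 * t)` to the log hazard; `(beta1,
  beta2)` is estimated by iterative linearization (Gauss–Newton on
  working covariates) with the covariance taken from the observed
  information of the full nonlinear model.
* **Model selection** (`correlation_screen()`, `stepwise_aic()`):
  stepwise AIC over everything but duration terms, then duration terms
  freed for every retained decay-eligible indicator regardless of
  significance; age forced in; deterministic name-based tie-breaks.
* **Internal validation** (`predicted_risk()`, `cumulative_dynamic_auc()`,
  `calibration_slope()`, `optimism_correct()`, `threshold_metrics()`,
  `validate_model()`): absolute risks from the Breslow baseline,
  cumulative/dynamic time-dependent AUC with IPCW, calibration slope,
  bootstrap optimism correction (Harrell's algorithm), and operating
  characteristics at 0.5/1/2% predicted-risk thresholds with exact
  Clopper–Pearson intervals.
* **Descriptives** (`reverse_km_median_followup()`,
  `age_standardized_cuminc()`, `cohort_incidence()`): reverse
  Kaplan–Meier follow-up and model-based cumulative incidence
  standardized to age 60.

## Worked example

```r
library(pdacrisk)

emr   <- generate_population(sim_config(n_subjects = 5000, seed = 1))
built <- build_analysis_dataset(emr)
d     <- subset(built$data, cohort == "insulin_init" & sex == "male")

sw <- stepwise_aic(d,
  candidates     = c("age", "hba1c", "hba1c_change", "weight",
                     "weight_change_pct", "cholesterol",
                     "acute_pancreatitis", "abdominal_pain"),
  forced         = "age",
  decay_eligible = c("acute_pancreatitis", "abdominal_pain"))
hr_at_lag(decay_effects(sw$fit)$acute_pancreatitis, c(0, 36))
```

```
   t      hr    lower    upper
1  0 5.25127 2.901262 9.504771
2 36 5.25127 3.382772 8.151844
```

The generator's ground truth for acute pancreatitis is a hazard ratio of
7.26 decaying to 6.63 at 36 months (decay rate 0.0025/month). At this
sample size the fitted decay rate lands on the non-negativity boundary —
a flat profile whose confidence intervals cover the truth at both lags;
the slow true decay needs a larger cohort to resolve (the shipped checks
recover it within 3 SE at n = 50,000). Discrimination and calibration at
36 months:

```r
risk <- predicted_risk(sw$fit, d, 36)
cumulative_dynamic_auc(risk, d$time, d$event, 36)$auc
#> [1] 0.7072956
calibration_slope(predict(sw$fit, d, type = "lp"), d$time, d$event)$slope
#> [1] 1
```

(The slope is exactly 1 on training data — the self-calibration identity;
apparent discrimination under the generator's default, 50x-inflated event
rate is moderate by construction.) Event counts here are inflated for
testability; set `event_inflation = 1` in `sim_config()` for the rare-event
regime (about 0.18% cumulative incidence at 12 months for the highest-risk
cohort at the reference covariate profile).

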