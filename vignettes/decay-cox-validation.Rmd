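---
title: "Risk models with decaying effects for pancreatic cancer after diabetes progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk models with decaying effects for pancreatic cancer after diabetes progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is rare but usually detected late.
Among people who already have diabetes, a *worsening* of glycemic control —
starting insulin, moving from one oral hypoglycemic drug to a combination,
or a jump of at least one HbA1c percentage point to 8% or more — marks a
moment at which PDAC risk is elevated and a risk model could plausibly
triage patients toward imaging. `pdacrisk` implements that modeling
pipeline end to end on electronic-medical-record (EMR)-shaped data: cohort
construction from relational tables, Cox models in which the effect of a
past diagnosis *decays* with the time since it was recorded, AIC-based
model selection with duration-term constraints, and internal validation
with bootstrap optimism correction.

Because individual-level data from the health system that motivated this
design are restricted, the package ships a synthetic EMR generator with
known ground truth. Every downstream stage is tested against that truth or
against independent oracles; nothing requires a download.

## The decaying-effect Cox model

For a binary predictor (say, acute pancreatitis) first recorded $t$ months
before cohort entry, the model contributes

$$\log HR(t) \;=\; \beta_1 \, I \, e^{-\beta_2 t},$$

to the log hazard: $\beta_1$ is the log hazard ratio of a *current*
diagnosis, and $\beta_2 \ge 0$ (per month) controls how quickly the
association fades. $\beta_2 = 0$ recovers an ordinary constant effect. The
covariate is assessed once, at the index date, and held fixed during
follow-up. With $\exp(\beta_1) = 7.26$ decaying to $6.63$ at 36 months,
$\beta_2 = \log(\log 7.26 / \log 6.63)/36 \approx 0.0025$ — the scale of
effect the model is designed to express.

### Estimation by iterative linearization

The pair $(\beta_1, \beta_2)$ enters the partial likelihood nonlinearly.
We fit it by a Gauss–Newton scheme: at outer iteration $k$, given
$\beta_2^{(k)}$, each decay covariate contributes two working columns

$$z_1 = I\,e^{-\beta_2^{(k)} t}, \qquad
  z_2 = -\beta_1^{(k)}\, I\, t\, e^{-\beta_2^{(k)} t},$$

a *linear* Cox model is fitted in (linear covariates, $z_1$, $z_2$), and
$\beta_1 \leftarrow \hat c_{z_1}$, $\beta_2 \leftarrow \beta_2^{(k)} +
\hat c_{z_2}$. Because the working design at a fixed point equals the
Jacobian of the nonlinear linear predictor, a converged fixed point is a
stationary point of the full partial likelihood; the test suite verifies
this by numerical differentiation and against a profile-likelihood grid.

Numerical choices worth knowing:

* **Ties.** Efron's correction is the default (EMR-scale data are heavily
  tied); Breslow is available for cross-checks against references that
  default to it. The two share one code path (Breslow is the Efron formula
  with the tie fraction fixed at zero).
* **Constraint.** $\beta_2$ is projected to $\ge 0$ ("decay, not growth");
  `nonneg_beta2 = FALSE` allows unconstrained diagnostics. At the boundary
  the working column of a rate whose step points outward is dropped for
  that iteration (a KKT freeze) — without this the iteration oscillates
  when the true rate is 0.
* **Steps and stopping.** Inner Newton–Raphson uses step-halving (up to
  10); convergence requires score norm and relative log-likelihood change
  below `tol` ($10^{-8}$), outer convergence a maximum parameter change
  below `tol`, with at most 100 outer iterations.
* **Covariance.** The $(\beta_1, \beta_2)$ covariance comes from the
  analytic observed information of the *full nonlinear* model at the
  solution, not from the last linearization, which would understate
  $\mathrm{Var}(\hat\beta_2)$. The cross-derivative corrections are
  verified against a numerical Hessian in the tests.
* **Degeneracies.** Zero-variance covariates and decay indicators with no
  positive subjects are rejected with the offending name; coefficients
  exceeding 20 in absolute value abort with a monotone-likelihood
  (separation) diagnosis.

Delta-method intervals for $HR(t) = \exp(\beta_1 e^{-\beta_2 t})$ use the
gradient $(e^{-\beta_2 t},\, -\beta_1 t e^{-\beta_2 t})$, so the "current"
and "3 years in the past" presentations are mutually consistent by
construction.

## Cohort construction

`identify_diabetes()` requires two outpatient diabetes diagnoses *and* one
qualifying outpatient lab (HbA1c $\ge 6.5$%, fasting glucose $\ge 126$,
or random glucose $\ge 200$ mg/dL) — inpatient and emergency-department
draws are excluded because acute illness inflates glucose — with age
$\ge 50$ at first evidence. First evidence is the earliest date of any
qualifying element.

`build_progression_cohorts()` derives three overlapping cohorts with index
dates: first insulin prescription; first day with two distinct oral
hypoglycemic classes prescribed simultaneously after a spell on exactly
one class (*simultaneous* = same calendar day by default — the strictest
reading, configurable via `combo_grace_days`); and the first outpatient
HbA1c $\ge 8.0$ exceeding some HbA1c within the prior 15 months by
$\ge 1.0$. An index within 90 days of first diabetes evidence is excluded
(such patients likely had unrecognized diabetes, so the timing of
progression is not interpretable).

Covariates are assessed on or before the index date: the *current* value
of each lab is the one most proximal to the index within 12 months;
changes compare it with the value closest to 12 months earlier inside a
3-to-15-month window (ties toward the earlier test). Weights outside
75–500 lbs and heights outside 48–84 inches are discarded before any use;
peak BMI uses the highest plausible weight ever recorded. A history of
both acute and chronic pancreatitis is classified as chronic. Rows with
any missing continuous covariate are excluded, with a warning when the
loss exceeds the 10% ceiling the complete-case design assumes.

Month arithmetic uses 30.4375 days/month throughout, and the 15-month
lookback is implemented as $15 \times 30.4375 = 456.5625$ days.

## What the synthetic generator does (and does not) emulate

`generate_population()` draws ground truth first — cohort qualification,
index dates, covariate values, condition histories with log-normal onset
lags, the true linear predictor, and a Weibull event time — then lays down
relational tables from which the builder can reconstruct everything. Its
defaults encode the study conditions the package targets: a predominantly
male population (3% female), age $\sim \mathcal N(64, 8)$ truncated at 50,
covariate locations and spreads matched to reported medians/IQRs for such
cohorts, condition prevalences typical of an older male diabetes
population in a large integrated health system, decaying effects
for acute pancreatitis (HR 7.26 → 6.63 at 36 months), abdominal pain
(3.02 → 2.35), and jaundice (20.4 → 3.06), and a baseline calibrated to a
0.18% 12-month cumulative incidence at the reference profile. Because
PDAC is rare, `event_inflation` (default 50) multiplies the baseline
hazard so that desk-scale cohorts contain enough events to exercise every
stage; set it to 1 for full-scale realism. Censoring combines a 120-month
administrative limit with a small exponential dropout (0.004/month) — the
source system's censoring process is not documented, so this is a free
parameter.

Three placement rules make membership *exactly* recoverable, and the
round-trip test (builder output versus truth) is exact by design:
non-qualifying subjects' HbA1c values stay within a ±0.45 band around a
subject-level base (no pair can show a ≥ 1.0 rise, and rises are drawn
with a 1.05 floor so rounding cannot undo qualification); oral drug
classes of non-combo subjects never share a calendar day; insulin appears
only for insulin initiators. The membership truth applies the builder's
own definitions to the emitted records — in particular, the 90-day and
age-50 rules are evaluated against the *effective* first evidence, which a
banded HbA1c value ≥ 6.5 recorded before the first diagnosis code
legitimately moves earlier.

Limitations to keep in mind when generalizing from green tests: covariates
are drawn independently (no realistic correlation structure); a
multi-cohort subject's planted lab pairs can interleave across index
dates, so extracted values occasionally differ from the subject-level
truth (faithful extraction, noisy covariates); effects are
proportional-hazards by construction; there is no competing mortality, no
coding noise, and no calendar trends. Passing tests demonstrate the
*machinery* is correct under known truth, not that real EMR data meet
these assumptions.

## Validation methodology

Discrimination uses the cumulative/dynamic time-dependent AUC: cases are
subjects with an observed event by the horizon, controls those event-free
beyond it, and censoring is handled by inverse-probability-of-censoring
weights from the reverse Kaplan–Meier of the censoring distribution. On
uncensored data the estimator reduces exactly to the concordant-pair
fraction. Its CI uses the two-sample U-statistic projection
(influence-function) variance of the weighted AUC; variability of the
estimated censoring weights is ignored, which is slightly conservative in
the direction of wider intervals at heavy censoring.

Calibration is summarized by the calibration slope — the coefficient of
the frozen linear predictor refitted as the sole covariate. On training
data the slope is 1 identically (score equation); below 1 on fresh data
indicates overfitting.

Optimism correction follows the bootstrap algorithm: resample subjects,
rerun the *entire* pipeline, evaluate each metric on the resample and on
the original data, and subtract the mean gap from the apparent value.
`B = 200` is the design default (midpoint of the 100–300 range the method
is normally run with); replicate seeds derive from the master seed, and a
replicate whose pipeline fails is dropped with a logged reason (more than
10% failing is an error). Rerunning selection inside every replicate is
the honest variant; the acceptance script uses a *fast mode* that refits
only the selected model's coefficients from a warm start and says so.

Threshold operating characteristics (sensitivity, specificity, PPV at
predicted-risk thresholds 0.5%, 1%, 2%) classify subjects with an event by
the horizon as outcome-positive and those followed beyond it event-free as
negative; subjects censored early without an event are excluded — the
design question has no documented answer, so an IPCW-weighted variant
(`ipcw = TRUE`, approximate Kish-effective-size CIs) is provided for
sensitivity analysis. CIs are exact Clopper–Pearson (closed Beta-quantile
form).

Age standardization of cumulative incidence is model-based: a Cox fit with
age as the sole covariate, evaluated at the standard age (60), i.e.
$1 - \exp\{-\hat H_0(\tau)\, e^{\hat\beta_{age}(60 - \bar a)}\}$. A
stratified direct standardization would be an alternative; the
model-based form was chosen because it remains stable in small (female-
scale) cohorts. Death is treated as censoring, not as a competing risk.

## Model selection

Stepwise AIC runs in two stages. Stage 1 considers all candidates except
duration parameters, with decay-eligible indicators entering as constant
effects; the single best add/drop move is applied until no move improves
the AIC, with alphabetical tie-breaks so results are invariant to input
order. Stage 2 frees the decay rate of every retained decay-eligible
indicator and refits — *regardless* of whether the AIC worsens: duration
terms accompany their indicator by design, not by significance. Age is
forced into all models. Collinearity is reduced beforehand by dropping,
within every pair correlated at $|r| \ge 0.8$, the member with the worse
univariate AIC. Sex-specific models are obtained by running the pipeline
on each sex subset.

## Worked example

```{r example, eval = FALSE}
library(pdacrisk)

emr <- generate_population(sim_config(n_subjects = 5000, seed = 1))
built <- build_analysis_dataset(emr)
d <- subset(built$data, cohort == "insulin_init" & sex == "male")

scr <- correlation_screen(d, c("age", "weight", "weight_change_pct",
                               "hba1c", "hba1c_change", "cholesterol"))
sw <- stepwise_aic(d, candidates = c(scr$retained, "acute_pancreatitis",
                                     "abdominal_pain"),
                   forced = "age",
                   decay_eligible = c("acute_pancreatitis",
                                      "abdominal_pain"))
sw$fit
hr_at_lag(decay_effects(sw$fit)$acute_pancreatitis, c(0, 36))

report <- validate_model(d, function(data) {
  fit_decay_cox(data, setdiff(sw$selected, sw$decay_selected),
                sw$decay_selected)
}, horizons = c(12, 36), B = 100, seed = 7)
report
```

## Problem sizes used by the shipped checks

The test suite exercises the decay fitter at up to $n = 50{,}000$ with
roughly a thousand events (20 seeds), the profile-likelihood oracle on a
51-point grid at $n = 6{,}000$, the cohort round trip at $n = 5{,}000$,
the null-model optimism bootstrap at $n = 500$ with $B = 100$, and the
shrinkage demonstration at 100 replicates of 30 noise covariates on
$n = 300$. The acceptance script simulates 40,000 subjects at the
*uninflated* event rate — so absolute risks sit in the regime where the
0.5/1/2% thresholds discriminate — fits and validates the male insulin
cohort with $B = 100$ fast-mode bootstrap, and recovers the
acute-pancreatitis decay pair from a separate 50,000-subject simulation.
These sizes are the package's choice of a desk-scale study; the test
suite, in contrast, mostly runs with the default 50x event inflation so
that small cohorts contain enough events.

## Known limitations

* Decay covariates are baseline-fixed; no time-varying covariates,
  stratification, frailty, or left truncation.
* The correlation screen is pairwise-greedy, not a joint VIF analysis.
* The AUC CI ignores censoring-weight variability; the bootstrap CI of the
  corrected c-statistic is percentile-based over replicates.
* Standardized incidence treats death as censoring (no Fine–Gray model).
* The generator's qualification flags are exact by construction, which is
  what makes the round trip a sharp test — but it also means the builder
  and generator share the cohort definitions; coding errors *common to
  both* would not be caught by that test alone (the hand-enumerated
  fixtures exist for exactly this reason).
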