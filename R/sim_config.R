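# Configuration for the synthetic EMR generator.
#
# Defaults emulate a predominantly male diabetes population drawn from a
# large integrated health system: covariate locations and spreads match
# reported medians/IQRs for such cohorts (converted to normal means/SDs),
# ground-truth effects match reported multivariable hazard ratios for the
# same risk factors, and the baseline event-time law is a Weibull (shape 1)
# calibrated so that the 12-month cumulative PDAC incidence at linear
# predictor 0 is 0.18%.  `event_inflation` (default 50) multiplies the
# baseline hazard so that desk-scale cohorts yield enough events to test on.

SIM_EPOCH <- as.Date("2000-01-01")

COHORT_KINDS <- c("insulin_init", "combo_oral", "hba1c_rise")

ORAL_CLASSES <- c("biguanide", "sulfonylurea", "thiazolidinedione",
                  "alpha_glucosidase_inhibitor", "dpp4_inhibitor",
                  "glp1_agonist")

CONDITION_NAMES <- c("acute_pancreatitis", "chronic_pancreatitis",
                     "abdominal_pain", "nafld", "heart_disease", "jaundice",
                     "alcoholism", "cirrhosis", "back_pain")

default_effects <- function() {
  list(
    age               = linear_effect(log(1.04), center = 64),
    weight            = linear_effect(log(0.96) / 10, center = 216),
    weight_change_pct = linear_effect(log(0.56) / 20, center = 0),
    hba1c             = linear_effect(log(1.04), center = 8.7),
    hba1c_change      = linear_effect(log(1.03), center = 0.2),
    cholesterol       = linear_effect(log(0.98) / 10, center = 163),
    smoking_current   = linear_effect(log(1.33), center = 0),
    alcoholism        = linear_effect(log(1.55), center = 0),
    acute_pancreatitis = decay_effect(log(7.26), solve_decay_rate(7.26, 6.63, 36)),
    abdominal_pain     = decay_effect(log(3.02), solve_decay_rate(3.02, 2.35, 36)),
    jaundice           = decay_effect(log(20.4), solve_decay_rate(20.4, 3.06, 36))
  )
}

default_covariate_dists <- function() {
  list(
    age        = list(mean = 64, sd = 8, min = 50, max = 90),
    weight_m   = list(mean = 216, sd = 45, min = 90, max = 480),
    weight_f   = list(mean = 196, sd = 43, min = 85, max = 470),
    height_m   = list(mean = 69.5, sd = 2.7, min = 60, max = 80),
    height_f   = list(mean = 64.5, sd = 2.5, min = 55, max = 76),
    weight_change_pct = list(mean = -0.43, sd = 4.3, min = -25, max = 25),
    hba1c      = list(mean = 8.3, sd = 1.5, min = 5.8, max = 13),
    hba1c_rise_current = list(mean = 9.0, sd = 1.0, min = 8.0, max = 12),
    hba1c_rise_delta   = list(mean = 1.5, sd = 0.5, min = 1.05, max = 3),
    hba1c_change = list(mean = 0.2, sd = 0.45, min = -0.9, max = 0.9),
    creatinine = list(mean = 1.1, sd = 0.37, min = 0.3, max = 6),
    cholesterol = list(mean = 163, sd = 41, min = 60, max = 400),
    bilirubin  = list(mean = 0.6, sd = 0.3, min = 0.1, max = 5),
    hemoglobin = list(mean = 13.8, sd = 1.6, min = 6, max = 20),
    rbc        = list(mean = 4.65, sd = 0.56, min = 2.5, max = 7),
    bilirubin_change_pct = list(mean = 0, sd = 33, min = -80, max = 150),
    rbc_change_pct       = list(mean = 0, sd = 5.9, min = -30, max = 30),
    smoking  = c(current = 0.27, former = 0.41, never = 0.19, missing = 0.13),
    drinking = c(no = 0.44, yes = 0.08, missing = 0.48),
    race     = c(white = 0.796, black = 0.174, asian = 0.004, other = 0.026),
    hispanic_fraction = 0.06
  )
}

default_condition_prevalences <- function() {
  c(acute_pancreatitis = 0.023, chronic_pancreatitis = 0.011,
    abdominal_pain = 0.158, nafld = 0.035, heart_disease = 0.45,
    jaundice = 0.0045, alcoholism = 0.33, cirrhosis = 0.021,
    back_pain = 0.164)
}

#' Configuration for the synthetic EMR generator
#'
#' All parameters have defaults describing the study conditions the package
#' is designed around: three overlapping diabetes-progression cohorts, rare
#' PDAC events (0.18% cumulative incidence over 12 months at the reference
#' covariate profile before inflation), decaying effects for acute
#' pancreatitis, abdominal pain and jaundice, and administrative censoring at
#' 120 months plus a small per-month dropout hazard.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param female_fraction Fraction female (the emulated health system is
#'   predominantly male; default 0.03).
#' @param seed Integer seed; identical `(config, seed)` gives byte-identical
#'   output.
#' @param baseline_shape,baseline_scale Weibull event-time law (months);
#'   `baseline_scale = NULL` calibrates the scale so that the cumulative
#'   incidence at `target_12m_incidence` is reached at 12 months for a
#'   subject at linear predictor 0 (before inflation).
#' @param target_12m_incidence See `baseline_scale`.
#' @param event_inflation Multiplier on the baseline hazard for test-scale
#'   runs (default 50; set to 1 for full-scale realism).
#' @param admin_censor_months Administrative censoring time after cohort
#'   entry, months.
#' @param dropout_rate Per-month hazard of loss to follow-up.
#' @param cohort_mix Named probabilities of qualifying for each progression
#'   definition (independent draws; overlap arises naturally).
#' @param cohort_loghr Named additive log hazard per cohort (applied for the
#'   subject's earliest cohort), expressing that insulin initiators carry the
#'   highest incidence.
#' @param nonprogressor_loghr Additive log hazard for diabetics who meet no
#'   progression definition.
#' @param frac_nondiabetic Fraction of subjects that fail the diabetes
#'   definition (single diagnosis code, non-qualifying labs).
#' @param frac_early_progressor Fraction of qualifying subjects whose index
#'   falls within 90 days of first diabetes evidence (excluded downstream).
#' @param missing_lab_rate Per cohort-row probability that a given lab pair
#'   (cholesterol, RBC, bilirubin) is not recorded, creating incomplete rows.
#' @param inpatient_lab_rate Fraction of subjects receiving extreme-valued
#'   inpatient labs that downstream code must ignore.
#' @param implausible_vital_rate Fraction of subjects with an out-of-range
#'   weight record (filtered downstream).
#' @param effects Named list of [linear_effect()] / [decay_effect()] ground
#'   truths keyed by covariate name.
#' @param covariate_dists,condition_prevalences,drug_prevalences
#'   Distribution parameters; see `default_covariate_dists()`.
#' @param onset_lag_meanlog,onset_lag_sdlog Log-normal parameters (months)
#'   for condition/prescription onset lags before the index date.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5000,
                       female_fraction = 0.03,
                       seed = 1L,
                       baseline_shape = 1,
                       baseline_scale = NULL,
                       target_12m_incidence = 0.0018,
                       event_inflation = 50,
                       admin_censor_months = 120,
                       dropout_rate = 0.004,
                       cohort_mix = c(insulin_init = 0.29, combo_oral = 0.27,
                                      hba1c_rise = 0.38),
                       cohort_loghr = c(insulin_init = 0, combo_oral = -0.6,
                                        hba1c_rise = -0.17),
                       nonprogressor_loghr = -0.8,
                       frac_nondiabetic = 0.02,
                       frac_early_progressor = 0.05,
                       missing_lab_rate = 0.02,
                       inpatient_lab_rate = 0.05,
                       implausible_vital_rate = 0.03,
                       effects = default_effects(),
                       covariate_dists = default_covariate_dists(),
                       condition_prevalences = default_condition_prevalences(),
                       drug_prevalences = c(ppi = 0.42, statin = 0.55,
                                            biguanide = 0.76,
                                            dpp4_inhibitor = 0.024),
                       onset_lag_meanlog = log(24),
                       onset_lag_sdlog = 1.0) {
  cfg <- as.list(environment())
  chk_prob <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("configuration error in '", nm, "': probabilities must lie in [0, 1]")
    }
  }
  if (!is.numeric(n_subjects) || n_subjects < 0 || n_subjects != round(n_subjects)) {
    stop("configuration error in 'n_subjects': must be a non-negative integer")
  }
  chk_prob(female_fraction, "female_fraction")
  chk_prob(cohort_mix, "cohort_mix")
  chk_prob(frac_nondiabetic, "frac_nondiabetic")
  chk_prob(frac_early_progressor, "frac_early_progressor")
  chk_prob(missing_lab_rate, "missing_lab_rate")
  chk_prob(inpatient_lab_rate, "inpatient_lab_rate")
  chk_prob(implausible_vital_rate, "implausible_vital_rate")
  chk_prob(condition_prevalences, "condition_prevalences")
  chk_prob(drug_prevalences, "drug_prevalences")
  if (!setequal(names(cohort_mix), COHORT_KINDS)) {
    stop("configuration error in 'cohort_mix': must name exactly ",
         paste(COHORT_KINDS, collapse = ", "))
  }
  if (dropout_rate < 0) {
    stop("configuration error in 'dropout_rate': hazard must be >= 0")
  }
  if (admin_censor_months <= 0) {
    stop("configuration error in 'admin_censor_months': must be > 0")
  }
  if (baseline_shape <= 0) {
    stop("configuration error in 'baseline_shape': must be > 0")
  }
  if (event_inflation <= 0) {
    stop("configuration error in 'event_inflation': must be > 0")
  }
  if (is.null(cfg$baseline_scale)) {
    cfg$baseline_scale <-
      12 / (-log1p(-target_12m_incidence))^(1 / baseline_shape)
  }
  if (cfg$baseline_scale <= 0) {
    stop("configuration error in 'baseline_scale': must be > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: n =", x$n_subjects, "; seed =", x$seed, "\n")
  cat("  Weibull baseline: shape", x$baseline_shape, ", scale",
      signif(x$baseline_scale, 5), "months; inflation", x$event_inflation, "x\n")
  cat("  cohort mix:", paste(sprintf("%s=%.2f", names(x$cohort_mix),
                                     x$cohort_mix), collapse = ", "), "\n")
  invisible(x)
}
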