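# Independent oracles and hand-built fixtures shared across the suite.

# Brute-force negative log partial likelihood by explicit risk-set products;
# written independently of the package's cumulative-sum implementation.
brute_force_neg_logpl <- function(lp, time, status, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sD <- sum(exp(lp[D]))
    sR <- sum(exp(lp[R]))
    ll <- ll + sum(lp[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sR)
    } else {
      for (l in seq_len(d) - 1) ll <- ll - log(sR - (l / d) * sD)
    }
  }
  -ll
}

# Brute-force concordant-pair AUC on uncensored data (cases = event by
# horizon, controls = survivors past it), ties counted half.
brute_force_auc <- function(risk, time, event, horizon) {
  cases <- which(time <= horizon & event == 1)
  ctrls <- which(time > horizon)
  num <- 0
  for (i in cases) {
    for (j in ctrls) {
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / (length(cases) * length(ctrls))
}

# Lightweight survival simulator with one decaying binary effect, written
# with plain exponential draws (independent of simulate_event_time()).
sim_decay_data <- function(n, beta1, beta2, base_rate = 0.002,
                           prev = 0.3, lag_rate = 1 / 24,
                           admin = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  I <- rbinom(n, 1, prev)
  lag <- ifelse(I == 1, rexp(n, lag_rate), 0)
  lp <- I * beta1 * exp(-beta2 * lag)
  t0 <- rexp(n, base_rate * exp(lp))
  data.frame(time = pmin(t0, admin), event = as.integer(t0 <= admin),
             ap = I, ap_lag = lag)
}

# Two-covariate proportional-hazards simulator for generic fitting tests.
sim_ph_data <- function(n, beta = c(0.8, 0.5), base_rate = 0.01,
                        censor_max = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  z <- rbinom(n, 1, 0.4)
  t0 <- rexp(n, base_rate * exp(beta[1] * x + beta[2] * z))
  cen <- runif(n, 0, censor_max)
  data.frame(time = pmin(t0, cen), event = as.integer(t0 <= cen),
             x = x, z = z)
}

# --- hand fixtures -----------------------------------------------------------

emr_shell <- function() {
  d0 <- as.Date("2000-01-01")
  list(
    patients = data.table::data.table(
      id = character(), sex = character(), birth_date = d0[0],
      race = character(), ethnicity = character(), smoking = character(),
      drinking = character()),
    diagnoses = data.table::data.table(
      id = character(), date = d0[0], condition = character(),
      setting = character()),
    prescriptions = data.table::data.table(
      id = character(), date = d0[0], drug_class = character()),
    labs = data.table::data.table(
      id = character(), date = d0[0], analyte = character(),
      value = numeric(), inpatient = logical()),
    vitals = data.table::data.table(
      id = character(), date = d0[0], weight_lbs = numeric(),
      height_in = numeric()),
    outcomes = data.table::data.table(
      id = character(), date = d0[0], pdac = integer())
  )
}

fx_day <- function(d) as.Date("2000-01-01") + d

fx_patient <- function(id, age = 60) {
  data.table::data.table(id = id, sex = "male",
                         birth_date = fx_day(-round(age * 365.25)),
                         race = "white", ethnicity = "non_hispanic",
                         smoking = "never", drinking = "no")
}

fx_dm_base <- function(id, glucose = 130) {
  list(
    dx = data.table::data.table(id = id, date = fx_day(c(0, 40)),
                                condition = "diabetes",
                                setting = "outpatient"),
    lab = data.table::data.table(id = id, date = fx_day(0),
                                 analyte = "glucose_fasting",
                                 value = glucose, inpatient = FALSE)
  )
}

# Six-subject fixture for the diabetes-identification rule conjunction.
# Expected inclusion enumerated by hand:
#   A: 2 outpatient dx + HbA1c 6.5 (boundary)      -> in, evidence day 0
#   B: 2 dx + inpatient glucose 250 only           -> out (inpatient lab)
#   C: 1 dx + fasting glucose 130                  -> out (one diagnosis)
#   D: 2 dx + fasting glucose 126 (boundary)       -> in
#   E: 2 dx + random glucose 200, age 49           -> out (age)
#   F: 2 dx + HbA1c 6.4                            -> out (no qualifying lab)
fixture_diabetes <- function() {
  emr <- emr_shell()
  dt <- data.table::data.table
  emr$patients <- data.table::rbindlist(list(
    fx_patient("A"), fx_patient("B"), fx_patient("C"), fx_patient("D"),
    fx_patient("E", age = 49), fx_patient("F")))
  emr$diagnoses <- dt(
    id = c("A", "A", "B", "B", "C", "D", "D", "E", "E", "F", "F"),
    date = fx_day(c(0, 30, 0, 30, 0, 0, 30, 0, 30, 0, 30)),
    condition = "diabetes", setting = "outpatient")
  emr$labs <- dt(
    id = c("A", "B", "C", "D", "E", "F"),
    date = fx_day(10),
    analyte = c("hba1c", "glucose_random", "glucose_fasting",
                "glucose_fasting", "glucose_random", "hba1c"),
    value = c(6.5, 250, 130, 126, 200, 6.4),
    inpatient = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  emr$outcomes <- dt(id = c("A", "B", "C", "D", "E", "F"),
                     date = fx_day(2000), pdac = 0L)
  class(emr) <- "raw_emr"
  emr
}

# Eight-subject fixture covering all three progression definitions and the
# 90-day exclusion.  Hand-enumerated membership:
#   P1 insulin day 200                          -> insulin_init @ 200
#   P2 insulin day 60                           -> excluded (90-day rule)
#   P3 biguanide d100; biguanide+sulfonylurea d400 -> combo_oral @ 400
#   P4 biguanide d100; sulfonylurea d400 (alone)   -> none (not same-day)
#   P5 HbA1c 7.0 d120, 8.0 d520 (gap 400)          -> hba1c_rise @ 520
#   P6 HbA1c 6.9 d100, 8.1 d600 (gap 500 > 15 mo)  -> none
#   P7 insulin d300; HbA1c 7.2 d150, 8.4 d450      -> insulin_init @ 300
#                                                     and hba1c_rise @ 450
#   P8 nothing                                      -> none
fixture_progression <- function() {
  emr <- emr_shell()
  dt <- data.table::data.table
  ids <- paste0("P", 1:8)
  emr$patients <- data.table::rbindlist(lapply(ids, fx_patient))
  base <- lapply(ids, fx_dm_base)
  emr$diagnoses <- data.table::rbindlist(lapply(base, `[[`, "dx"))
  labs <- lapply(base, `[[`, "lab")
  labs <- c(labs, list(
    dt(id = "P5", date = fx_day(c(120, 520)), analyte = "hba1c",
       value = c(7.0, 8.0), inpatient = FALSE),
    dt(id = "P6", date = fx_day(c(100, 600)), analyte = "hba1c",
       value = c(6.9, 8.1), inpatient = FALSE),
    dt(id = "P7", date = fx_day(c(150, 450)), analyte = "hba1c",
       value = c(7.2, 8.4), inpatient = FALSE)))
  emr$labs <- data.table::rbindlist(labs)
  emr$prescriptions <- dt(
    id = c("P1", "P2", "P3", "P3", "P3", "P4", "P4", "P4", "P7"),
    date = fx_day(c(200, 60, 100, 400, 400, 20, 100, 400, 300)),
    drug_class = c("insulin", "insulin", "biguanide", "biguanide",
                   "sulfonylurea", "biguanide", "biguanide", "sulfonylurea",
                   "insulin"))
  emr$outcomes <- dt(id = ids, date = fx_day(2000), pdac = 0L)
  class(emr) <- "raw_emr"
  emr
}

expected_membership <- function() {
  data.frame(
    id = c("P1", "P3", "P5", "P7", "P7"),
    cohort = c("insulin_init", "combo_oral", "hba1c_rise", "insulin_init",
               "hba1c_rise"),
    index_day = c(200, 400, 520, 300, 450),
    stringsAsFactors = FALSE)
}
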