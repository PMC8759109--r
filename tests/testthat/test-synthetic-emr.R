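test_that("identical config and seed give byte-identical tables", {
  cfg <- sim_config(n_subjects = 400, seed = 77)
  e1 <- generate_population(cfg)
  e2 <- generate_population(cfg)
  for (nm in c("patients", "diagnoses", "prescriptions", "labs", "vitals",
               "outcomes", "truth")) {
    expect_identical(e1[[nm]], e2[[nm]], label = nm)
  }
})

test_that("n_subjects = 0 gives empty tables with headers only", {
  emr <- generate_population(sim_config(n_subjects = 0, seed = 1))
  expect_identical(nrow(emr$patients), 0L)
  expect_identical(nrow(emr$labs), 0L)
  expect_true(all(c("id", "date", "analyte", "value", "inpatient") %in%
                    names(emr$labs)))
})

test_that("zero condition prevalences leave only diabetes diagnoses", {
  cfg <- sim_config(n_subjects = 300, seed = 5,
                    condition_prevalences = stats::setNames(
                      rep(0, length(default_condition_prevalences())),
                      names(default_condition_prevalences())),
                    effects = list(age = linear_effect(log(1.04), 64)))
  emr <- generate_population(cfg)
  expect_identical(unique(emr$diagnoses$condition), "diabetes")
})

test_that("invalid configuration names the offending field", {
  expect_error(sim_config(female_fraction = 1.4), "female_fraction")
  expect_error(sim_config(dropout_rate = -1), "dropout_rate")
  expect_error(sim_config(admin_censor_months = 0), "admin_censor_months")
  expect_error(sim_config(n_subjects = -2), "n_subjects")
})

test_that("referential integrity: child tables only reference known patients", {
  emr <- generate_population(sim_config(n_subjects = 500, seed = 8))
  ids <- emr$patients$id
  for (nm in c("diagnoses", "prescriptions", "labs", "vitals", "outcomes")) {
    expect_true(all(emr[[nm]]$id %in% ids), label = nm)
  }
  expect_identical(nrow(emr$outcomes), length(ids))   # one outcome row per id
})

test_that("exponential closed form: event fraction matches 1 - exp(-t/scale)", {
  set.seed(44)
  n <- 200000
  scale <- 120
  st <- simulate_event_time(rep(0, n), shape = 1, scale = scale,
                            dropout_rate = 0, admin_censor_months = 60)
  p_true <- 1 - exp(-60 / scale)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(st$event) - p_true), 3 * se)
})

test_that("12-month incidence calibration: 0.18% at linear predictor zero", {
  set.seed(45)
  cfg <- sim_config(n_subjects = 1, seed = 1, event_inflation = 1)
  n <- 1e6
  st <- simulate_event_time(rep(0, n), shape = cfg$baseline_shape,
                            scale = cfg$baseline_scale, dropout_rate = 0,
                            admin_censor_months = 12)
  p <- 0.0018
  expect_lt(abs(mean(st$event) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a decay term with beta2 = 0 acts as a constant linear effect", {
  set.seed(46)
  n <- 100000
  lag <- rexp(n, 1 / 24)
  de <- decay_effect(0.7, 0)
  set.seed(146)
  s1 <- simulate_event_time(rep(0, n),
                            decay_terms = list(list(effect = de, lag = lag)),
                            shape = 1, scale = 400, dropout_rate = 0,
                            admin_censor_months = 60)
  set.seed(146)
  s2 <- simulate_event_time(rep(0.7, n), shape = 1, scale = 400,
                            dropout_rate = 0, admin_censor_months = 60)
  expect_identical(s1$time, s2$time)   # same RNG stream, same law
})

test_that("empirical hazard ratio at fixed lag converges to the decay form", {
  set.seed(47)
  n <- 150000
  b1 <- log(4); b2 <- 0.03; lag <- 18
  I <- rbinom(n, 1, 0.5)
  st <- simulate_event_time(
    I * 0, decay_terms = list(list(effect = decay_effect(b1, b2),
                                   lag = ifelse(I == 1, lag, 1e6))),
    shape = 1, scale = 2000, dropout_rate = 0, admin_censor_months = 24)
  d <- data.frame(time = st$time, event = st$event, I = I)
  fit <- fit_linear_cox(d, "I")
  want <- b1 * exp(-b2 * lag)
  expect_lt(abs(fit$coefficients[["I"]] - want), 3 * fit$se[["I"]])
})

test_that("marginal covariate summaries track the configured targets", {
  emr <- generate_population(sim_config(n_subjects = 4000, seed = 10))
  tr <- emr$truth
  expect_lt(abs(median(tr$weight[tr$sex == "male"]) - 216), 4)
  expect_lt(abs(median(tr$cholesterol) - 163), 4)
  expect_lt(abs(median(tr$creatinine) - 1.1), 0.1)
  expect_lt(abs(mean(tr$sex == "female") - 0.03), 0.015)
  ap <- mean(tr$acute_pancreatitis == 1 | tr$chronic_pancreatitis == 1)
  expect_lt(abs(ap - 0.034), 0.012)   # acute+chronic combined draw
})

test_that("with all effects zero the simulated KM matches the Weibull law", {
  cfg <- sim_config(n_subjects = 8000, seed = 12,
                    effects = list(),
                    cohort_loghr = c(insulin_init = 0, combo_oral = 0,
                                     hba1c_rise = 0),
                    nonprogressor_loghr = 0, dropout_rate = 0)
  emr <- generate_population(cfg)
  tr <- emr$truth
  km <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = tr)
  scale_infl <- cfg$baseline_scale / cfg$event_inflation
  for (tt in c(12, 36, 60)) {
    s_hat <- summary(km, times = tt)$surv
    s_true <- exp(-tt / scale_infl)
    se <- summary(km, times = tt)$std.err
    expect_lt(abs(s_hat - s_true), 4 * se)
  }
})

test_that("EMR bundles round-trip through delimited text", {
  emr <- generate_population(sim_config(n_subjects = 120, seed = 3))
  dir <- withr::local_tempdir()
  write_emr(emr, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_emr(dir)
  expect_equal(as.data.frame(back$patients), as.data.frame(emr$patients))
  expect_equal(as.data.frame(back$labs), as.data.frame(emr$labs))
  expect_equal(back$outcomes$pdac, emr$outcomes$pdac)
})
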