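test_that("diabetes identification applies the rule conjunction (6-subject fixture)", {
  emr <- fixture_diabetes()
  diab <- identify_diabetes(emr)
  expect_setequal(diab$id, c("A", "D"))
  # first evidence = earliest qualifying element (diagnosis at day 0)
  expect_equal(as.numeric(diab$first_dm_date - fx_day(0)), c(0, 0))
})

test_that("progression cohorts and 90-day exclusion match the hand enumeration", {
  emr <- fixture_progression()
  diab <- identify_diabetes(emr)
  expect_setequal(diab$id, paste0("P", 1:8))
  coh <- build_progression_cohorts(emr, diab)
  want <- expected_membership()
  got <- as.data.frame(coh[, c("id", "cohort")])
  got$index_day <- as.numeric(coh$index_date - fx_day(0))
  got <- got[order(got$cohort, got$id), ]
  want <- want[order(want$cohort, want$id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got[c("id", "cohort", "index_day")], want)
})

test_that("HbA1c rise boundaries: exact 1.0 rise to exactly 8.0 qualifies; a 15-month-plus gap does not", {
  emr <- fixture_progression()
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab)
  ris <- coh[coh$cohort == "hba1c_rise", ]
  expect_true("P5" %in% ris$id)     # 7.0 -> 8.0, gap 400 days
  expect_false("P6" %in% ris$id)    # gap 500 days exceeds 15 months
})

test_that("combo grace window is configurable", {
  emr <- fixture_progression()
  diab <- identify_diabetes(emr)
  # P4: biguanide d100, sulfonylurea d400; within a 300-day grace window the
  # two classes count as simultaneous
  coh <- build_progression_cohorts(emr, diab, combo_grace_days = 300)
  expect_true("P4" %in% coh[coh$cohort == "combo_oral", ]$id)
})

test_that("covariate windows: proximal labs, percent changes, vital plausibility", {
  emr <- fixture_progression()
  dt <- data.table::data.table
  # P1 (index day 200): weight 210 at day -196 (13 months before index),
  # 200 at index; implausible 520 lbs record must be ignored everywhere
  emr$vitals <- dt(id = "P1", date = fx_day(c(-196, 150, 200)),
                   weight_lbs = c(210, 520, 200), height_in = c(70, NA, NA))
  emr$labs <- rbind(emr$labs, dt(
    id = "P1", date = fx_day(c(-165, 195)), analyte = "cholesterol",
    value = c(180, 162), inpatient = FALSE))
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab)
  ds <- extract_covariates(emr, coh)
  p1 <- ds[ds$id == "P1", ]
  expect_equal(p1$weight, 200)
  expect_equal(p1$weight_change_pct, 100 * (200 - 210) / 210,
               tolerance = 1e-12)           # -4.76%
  expect_equal(p1$peak_bmi, 703 * 210 / 70^2, tolerance = 1e-12)
  expect_equal(p1$cholesterol, 162)
  # prior cholesterol at gap 360 days sits inside the 3-15-month window
  expect_equal(p1$cholesterol, 162)
  expect_equal(ds[ds$id == "P1", "age"], (200 + round(60 * 365.25)) / 365.25,
               tolerance = 1e-6)
})

test_that("all lags are non-negative and every current lab predates its index", {
  emr <- generate_population(sim_config(n_subjects = 800, seed = 14))
  res <- suppressWarnings(build_analysis_dataset(emr,
                                                 apply_exclusions = FALSE))
  ds <- res$data
  lagcols <- grep("_lag$", names(ds), value = TRUE)
  for (lc in lagcols) {
    expect_true(all(is.na(ds[[lc]]) | ds[[lc]] >= 0), label = lc)
    ind <- sub("_lag$", "", lc)
    expect_true(all(ds[[ind]] == 0 | !is.na(ds[[lc]])),
                label = paste("lag defined when", ind, "= 1"))
  }
  expect_true(all(ds$time > 0))
})

test_that("cohort membership recovered from simulator output equals the ground truth", {
  emr <- generate_population(sim_config(n_subjects = 2000, seed = 15))
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab)
  tr <- emr$truth
  for (k in c("insulin_init", "combo_oral", "hba1c_rise")) {
    want <- tr[tr[[paste0("member_", k)]] == TRUE, ]
    got <- coh[coh$cohort == k, ]
    expect_setequal(got$id, want$id)
    m <- merge(data.frame(id = want$id,
                          index = want[[paste0("index_", k)]]),
               as.data.frame(got[, c("id", "index_date")]), by = "id")
    expect_identical(m$index, m$index_date)
  }
  # union of cohorts never exceeds the diabetic set
  expect_true(all(coh$id %in% diab$id))
  # per-cohort index dates are unique per subject
  expect_false(any(duplicated(as.data.frame(coh)[c("id", "cohort")])))
})

test_that("cohort building is deterministic given the same EMR", {
  emr <- generate_population(sim_config(n_subjects = 500, seed = 16))
  r1 <- suppressWarnings(build_analysis_dataset(emr))
  r2 <- suppressWarnings(build_analysis_dataset(emr))
  expect_identical(r1$data, r2$data)
})

test_that("chronic pancreatitis overrides a joint acute history", {
  emr <- fixture_progression()
  dt <- data.table::data.table
  emr$diagnoses <- rbind(emr$diagnoses, dt(
    id = "P1", date = fx_day(c(-100, -50)),
    condition = c("acute_pancreatitis", "chronic_pancreatitis"),
    setting = "outpatient"))
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab)
  ds <- extract_covariates(emr, coh)
  p1 <- ds[ds$id == "P1", ]
  expect_identical(p1$acute_pancreatitis, 0L)
  expect_identical(p1$chronic_pancreatitis, 1L)
  expect_equal(p1$chronic_pancreatitis_lag, 250 / 30.4375, tolerance = 1e-10)
})

test_that("exclude_incomplete counts, retains and warns correctly", {
  base <- data.frame(age = rnorm(10) + 60, weight = rnorm(10) + 200,
                     hba1c = rnorm(10) + 8)
  # complete data: nothing excluded
  r0 <- exclude_incomplete(base, continuous = names(base))
  expect_identical(nrow(r0$data), 10L)
  expect_identical(sum(r0$report$n_missing), 0L)
  # 1 of 10 missing cholesterol: 9 retained, report names it
  d1 <- base
  d1$cholesterol <- c(NA, rnorm(9) + 160)
  r1 <- exclude_incomplete(d1, continuous = names(d1))
  expect_identical(nrow(r1$data), 9L)
  expect_identical(
    r1$report$n_missing[r1$report$covariate == "cholesterol"], 1L)
  # 2 of 10 rows missing: warning at 20% > 10%
  d2 <- base
  d2$hba1c[1:2] <- NA
  expect_warning(r2 <- exclude_incomplete(d2, continuous = names(d2)),
                 "10%")
  expect_identical(nrow(r2$data), 8L)
})

test_that("a subject without an outcomes row is a data-integrity error", {
  emr <- fixture_progression()
  emr$outcomes <- emr$outcomes[emr$outcomes$id != "P1", ]
  diab <- identify_diabetes(emr)
  coh <- build_progression_cohorts(emr, diab)
  expect_error(extract_covariates(emr, coh), "outcomes row")
})

test_that("analysis tables and fit reports serialize to delimited/structured text", {
  emr <- generate_population(sim_config(n_subjects = 400, seed = 90))
  built <- suppressWarnings(build_analysis_dataset(emr))
  dir <- withr::local_tempdir()
  paths <- write_analysis_tables(built, dir)
  expect_true(any(grepl("analysis_insulin_init_male.csv", paths)))
  expect_true(file.exists(file.path(dir, "exclusions.yaml")))
  back <- data.table::fread(grep("insulin_init_male", paths, value = TRUE))
  expect_gt(nrow(back), 0)

  d <- sim_decay_data(2000, beta1 = 1.5, beta2 = 0.05, seed = 91)
  fit <- fit_decay_cox(d, character(0), "ap")
  p <- file.path(dir, "fit.yaml")
  write_fit_report(fit, p)
  rep_ <- yaml::read_yaml(p)
  expect_equal(rep_$aic, fit$aic, tolerance = 1e-8)
  expect_equal(rep_$decay_effects[[1]]$hr_current,
               exp(fit$decay$ap$beta1), tolerance = 1e-8)
})
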