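test_that("predicted risk reproduces hand Breslow arithmetic on a 3-event fixture", {
  # subjects: times 1, 2, 3 (all events), lp known; Breslow increments are
  # d_k / sum(risk-set weights) on the centered lp scale
  d <- data.frame(time = c(1, 2, 3), event = c(1L, 1L, 1L),
                  x = c(0.5, -0.4, 0.2))
  fit <- fit_linear_cox(d, "x")
  b <- fit$coefficients[["x"]]
  w <- exp(b * d$x - mean(b * d$x))
  h <- c(1 / sum(w), 1 / sum(w[2:3]), 1 / w[3])   # d_k / S0(t_k)
  H <- cumsum(h)
  # baseline subject (lp = mean): risk = 1 - exp(-H)
  risk2 <- predicted_risk(fit, data.frame(x = mean(d$x)), 2)
  expect_equal(risk2, 1 - exp(-H[2]), tolerance = 1e-10)
  # centered formula with a covariate shift
  riskx <- predicted_risk(fit, data.frame(x = 1), 2)
  expect_equal(riskx, 1 - exp(-H[2] * exp(b * 1 - mean(b * d$x))),
               tolerance = 1e-10)
})

test_that("horizon 0 gives zero risk; beyond the last event time errors", {
  d <- sim_ph_data(200, seed = 61)
  fit <- fit_linear_cox(d, c("x", "z"))
  expect_equal(predicted_risk(fit, d[1:3, ], 0), c(0, 0, 0))
  expect_error(predicted_risk(fit, d, max(d$time) * 2 + 1), "maximum usable")
})

test_that("AUC equals the brute-force pair fraction on uncensored fixtures", {
  set.seed(62)
  for (rep in 1:3) {
    n <- 40
    risk <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    time <- sample(1:50, n, replace = TRUE)
    event <- rep(1L, n)                                      # uncensored
    horizon <- 25
    if (!any(time <= horizon) || !any(time > horizon)) next
    got <- cumulative_dynamic_auc(risk, time, event, horizon)$auc
    expect_equal(got, brute_force_auc(risk, time, event, horizon),
                 tolerance = 1e-12)
  }
})

test_that("a perfectly separating score gives AUC 1; a null score gives 0.5", {
  time <- c(rep(5, 30), rep(40, 30))
  event <- rep(1L, 60)
  risk <- c(rep(0.9, 30), rep(0.1, 30))
  expect_equal(cumulative_dynamic_auc(risk, time, event, 20)$auc, 1)
  set.seed(63)
  n <- 10000
  t0 <- rexp(n, 0.03)
  d <- data.frame(time = pmin(t0, 60), event = as.integer(t0 <= 60))
  a <- cumulative_dynamic_auc(runif(n), d$time, d$event, 24)
  expect_lt(abs(a$auc - 0.5), 3 * a$se)
})

test_that("degenerate case/control splits raise an error", {
  expect_error(cumulative_dynamic_auc(runif(5), rep(1, 5), rep(1L, 5), 10),
               "AUC undefined")
})

test_that("calibration slope is exactly 1 on training data and halves under doubling", {
  d <- sim_ph_data(1500, seed = 64)
  fit <- fit_linear_cox(d, c("x", "z"))
  s <- calibration_slope(fit$lp, d$time, d$event)
  expect_lt(abs(s$slope - 1), 1e-6)
  s2 <- calibration_slope(2 * fit$lp, d$time, d$event)
  expect_equal(s2$slope, s$slope / 2, tolerance = 1e-6)
  expect_error(calibration_slope(rep(1, nrow(d)), d$time, d$event),
               "zero variance")
})

test_that("threshold metrics match the hand-enumerated 3-subject example", {
  tm <- threshold_metrics(risk = c(0.006, 0.004, 0.02),
                          time = c(6, 40, 6), event = c(1L, 0L, 1L),
                          horizon = 12, threshold = 0.01)
  expect_equal(tm$estimate[tm$metric == "sensitivity"], 0.5)
  expect_equal(tm$estimate[tm$metric == "specificity"], 1.0)
  expect_equal(tm$estimate[tm$metric == "ppv"], 1.0)
})

test_that("Clopper-Pearson intervals equal the Beta-quantile closed form", {
  expect_equal(unname(clopper_pearson(1, 1)), c(0.025, 1), tolerance = 1e-12)
  expect_equal(unname(clopper_pearson(0, 10)),
               c(0, qbeta(0.975, 1, 10)), tolerance = 1e-12)
  # agreement with the inversion performed by binom.test
  for (x in c(0, 3, 7, 10)) {
    bt <- stats::binom.test(x, 10)$conf.int
    expect_equal(unname(clopper_pearson(x, 10)), as.numeric(bt),
                 tolerance = 1e-9)
  }
})

test_that("sensitivity falls and specificity rises across increasing thresholds", {
  set.seed(65)
  n <- 3000
  x <- rnorm(n)
  t0 <- rexp(n, 0.005 * exp(0.8 * x))
  d <- data.frame(time = pmin(t0, 60), event = as.integer(t0 <= 60), x = x)
  fit <- fit_linear_cox(d, "x")
  risk <- predicted_risk(fit, d, 36)
  tms <- lapply(c(0.005, 0.01, 0.02), function(th)
    threshold_metrics(risk, d$time, d$event, 36, th))
  sens <- vapply(tms, function(t) t$estimate[t$metric == "sensitivity"],
                 numeric(1))
  spec <- vapply(tms, function(t) t$estimate[t$metric == "specificity"],
                 numeric(1))
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("optimism is exactly zero for a data-independent pipeline", {
  d <- sim_ph_data(300, seed = 66)
  const_pipe <- function(data) structure(list(), class = "const_fit")
  metric <- list(c30 = function(fit, data) 0.5)
  oc <- optimism_correct(d, const_pipe, metric, B = 20, seed = 1)
  expect_identical(oc$optimism, 0)
  expect_identical(oc$corrected, oc$apparent)
})

test_that("optimism correction is reproducible under the same seed", {
  d <- sim_ph_data(400, seed = 67)
  pipe <- function(data) fit_linear_cox(data, c("x", "z"))
  metric <- list(
    c24 = function(fit, data) {
      cumulative_dynamic_auc(predicted_risk(fit, data, 24), data$time,
                             data$event, 24)$auc
    })
  o1 <- optimism_correct(d, pipe, metric, B = 10, seed = 42)
  o2 <- optimism_correct(d, pipe, metric, B = 10, seed = 42)
  expect_identical(o1, o2)
  o3 <- optimism_correct(d, pipe, metric, B = 10, seed = 43)
  expect_false(identical(o1$optimism, o3$optimism))
})

test_that("confidence intervals widen as the sample shrinks", {
  set.seed(68)
  n <- 4000
  x <- rnorm(n)
  t0 <- rexp(n, 0.01 * exp(0.7 * x))
  d <- data.frame(time = pmin(t0, 60), event = as.integer(t0 <= 60), x = x)
  fit <- fit_linear_cox(d, "x")
  risk <- predicted_risk(fit, d, 36)
  a_big <- cumulative_dynamic_auc(risk, d$time, d$event, 36)
  sub <- 1:400
  a_small <- cumulative_dynamic_auc(risk[sub], d$time[sub], d$event[sub], 36)
  expect_gt(diff(a_small$ci), diff(a_big$ci))
  t_big <- threshold_metrics(risk, d$time, d$event, 36, 0.2)
  t_small <- threshold_metrics(risk[sub], d$time[sub], d$event[sub], 36, 0.2)
  w_big <- t_big$upper - t_big$lower
  w_small <- t_small$upper - t_small$lower
  expect_true(all(w_small >= w_big - 1e-12))
})
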