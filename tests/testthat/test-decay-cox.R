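test_that("decay parameters are recovered within 3 SE (single seed)", {
  d <- sim_decay_data(20000, beta1 = 2, beta2 = 0.02, seed = 31)
  fit <- fit_decay_cox(d, character(0), "ap")
  de <- fit$decay$ap
  expect_lt(abs(de$beta1 - 2), 3 * sqrt(de$vcov[1, 1]))
  expect_lt(abs(de$beta2 - 0.02), 3 * sqrt(de$vcov[2, 2]))
})

test_that("beta2 = 0 data reduce to the plain indicator fit", {
  d <- sim_decay_data(8000, beta1 = 1, beta2 = 0, seed = 7)
  dec <- fit_decay_cox(d, character(0), "ap")
  lin <- fit_linear_cox(d, "ap")
  expect_lt(abs(dec$decay$ap$beta1 - lin$coefficients[["ap"]]), 1e-3)
  z <- dec$decay$ap$beta2 / sqrt(dec$decay$ap$vcov[2, 2])
  expect_lt(z, 2.5)   # decay not significantly > 0
})

test_that("solution attains the profile-likelihood optimum over a beta2 grid", {
  d <- sim_decay_data(6000, beta1 = 1.5, beta2 = 0.04, seed = 13)
  fit <- fit_decay_cox(d, character(0), "ap")
  grid <- seq(0, 0.25, by = 0.005)
  prof <- vapply(grid, function(b2) {
    d2 <- d
    d2$z1 <- d$ap * exp(-b2 * d$ap_lag)
    fit_linear_cox(d2, "z1")$loglik
  }, numeric(1))
  expect_gte(fit$loglik, max(prof) - 1e-6)
})

test_that("the returned solution is a stationary point of the full model", {
  d <- sim_decay_data(4000, beta1 = 1.5, beta2 = 0.05, seed = 17)
  d$x <- rnorm(nrow(d))
  fit <- fit_decay_cox(d, "x", "ap")
  th <- fit$coefficients
  nll <- function(p) {
    lp <- d$x * p[1] + d$ap * p[2] * exp(-p[3] * d$ap_lag)
    neg_log_partial_likelihood(lp, d$time, d$event)
  }
  h <- 1e-6
  g <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (nll(th + e) - nll(th - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)), 1e-3)   # numerical-differencing noise floor
})

test_that("analytic observed information matches a numerical Hessian", {
  d <- sim_decay_data(3000, beta1 = 1.5, beta2 = 0.05, seed = 19)
  fit <- fit_decay_cox(d, character(0), "ap")
  th <- fit$coefficients
  nll <- function(p) {
    lp <- d$ap * p[1] * exp(-p[2] * d$ap_lag)
    neg_log_partial_likelihood(lp, d$time, d$event)
  }
  h <- 1e-5
  H <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- numeric(2); ei[i] <- h
      ej <- numeric(2); ej[j] <- h
      H[i, j] <- (nll(th + ei + ej) - nll(th + ei - ej) -
                    nll(th - ei + ej) + nll(th - ei - ej)) / (4 * h * h)
    }
  }
  expect_lt(max(abs(H - fit$info)) / max(abs(fit$info)), 1e-3)
})

test_that("a decay covariate with no positive indicators is rejected", {
  d <- sim_decay_data(100, beta1 = 1, beta2 = 0.02, seed = 3)
  d$ap <- 0
  expect_error(fit_decay_cox(d, character(0), "ap"), "no positive")
})

test_that("hr_at_lag closed forms: lag zero, no decay, delta-method CI", {
  de <- decay_effect(log(2), 0.05, vcov = diag(c(0.01, 1e-4)))
  at0 <- hr_at_lag(de, 0)
  expect_equal(at0$hr, 2)
  expect_equal(at0$lower, exp(log(2) - qnorm(0.975) * 0.1))
  flat <- decay_effect(log(3), 0)
  expect_equal(hr_at_lag(flat, c(0, 12, 60))$hr, rep(3, 3))
  expect_error(hr_at_lag(de, -1), "non-negative")
})

test_that("current/3-years-past hazard-ratio pairs are mutually consistent", {
  b2 <- solve_decay_rate(7.26, 6.63, 36)
  de <- decay_effect(log(7.26), b2)
  expect_equal(hr_at_lag(de, 36)$hr, 6.63, tolerance = 1e-12)
  expect_equal(hr_at_lag(de, 0)$hr, 7.26, tolerance = 1e-12)
})
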