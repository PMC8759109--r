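test_that("a duplicated covariate is screened out with r = 1", {
  d <- sim_ph_data(400, seed = 51)
  d$x2 <- d$x
  cs <- correlation_screen(d, c("x", "x2", "z"))
  expect_length(cs$retained, 2)
  expect_identical(nrow(cs$dropped), 1L)
  expect_equal(abs(cs$dropped$r), 1)
})

test_that("independent covariates survive screening at the 0.8 threshold", {
  set.seed(52)
  d <- sim_ph_data(1000, seed = 52)
  d$a <- rnorm(1000)
  d$b <- rnorm(1000)
  cs <- correlation_screen(d, c("x", "z", "a", "b"))
  expect_setequal(cs$retained, c("x", "z", "a", "b"))
})

test_that("threshold 0 keeps exactly one covariate per correlation component", {
  d <- sim_ph_data(500, seed = 53)
  d$a <- rnorm(500)
  d$b <- rnorm(500)
  cs <- correlation_screen(d, c("x", "z", "a", "b"), r_threshold = 0)
  expect_length(cs$retained, 1)
})

test_that("stepwise AIC finds a strong predictor among noise", {
  set.seed(54)
  hits <- replicate(20, {
    n <- 2000
    x <- rnorm(n)
    noise <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("n", 1:6)))
    t0 <- rexp(n, 0.02 * exp(0.8 * x))
    d <- data.frame(time = pmin(t0, 60), event = as.integer(t0 <= 60),
                    x = x, noise)
    sw <- suppressWarnings(
      stepwise_aic(d, candidates = c("x", paste0("n", 1:6))))
    "x" %in% sw$selected
  })
  expect_gte(mean(hits), 0.95)
})

test_that("forced-in covariates are always present", {
  d <- sim_ph_data(500, seed = 55)
  d$age <- rnorm(500, 64, 8)
  sw <- suppressWarnings(
    stepwise_aic(d, candidates = c("x", "z"), forced = "age"))
  expect_true("age" %in% sw$selected)
})

test_that("stage-1 AIC is non-increasing and the trail records both stages", {
  d <- sim_decay_data(4000, beta1 = 1.5, beta2 = 0.05, seed = 56)
  d$x <- rnorm(nrow(d)) + 0.3 * d$ap
  sw <- stepwise_aic(d, candidates = c("x", "ap"), decay_eligible = "ap")
  s1 <- sw$trail[sw$trail$stage == 1, ]
  expect_true(all(diff(s1$aic) <= 1e-10))
  expect_true("ap" %in% sw$decay_selected)
  expect_s3_class(sw$fit, "decay_cox_fit")
})

test_that("retained decay indicators get a duration term even when AIC worsens", {
  # beta2 truly 0: freeing it costs one parameter, so stage-2 AIC rises,
  # yet the duration term must still be present
  d <- sim_decay_data(3000, beta1 = 1.2, beta2 = 0, seed = 57)
  sw <- stepwise_aic(d, candidates = "ap", decay_eligible = "ap")
  aic1 <- utils::tail(sw$trail$aic[sw$trail$stage == 1], 1)
  aic2 <- sw$trail$aic[sw$trail$stage == 2]
  expect_length(aic2, 1)
  expect_gte(aic2, aic1 - 1e-8)      # one wasted df: AIC cannot improve much
  expect_true("ap" %in% names(sw$fit$decay))
})

test_that("selection output is invariant to candidate ordering and rerun", {
  d <- sim_ph_data(800, seed = 58)
  d$a <- rnorm(800)
  s1 <- suppressWarnings(stepwise_aic(d, candidates = c("x", "z", "a")))
  s2 <- suppressWarnings(stepwise_aic(d, candidates = c("a", "z", "x")))
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$trail, s2$trail)
  expect_identical(s1$fit$coefficients, s2$fit$coefficients)
})

test_that("when nothing improves the forced model a warning is raised", {
  set.seed(59)
  n <- 400
  d <- data.frame(time = rexp(n, 0.05), event = 1L, flat = 1)
  # a degenerate candidate can never enter, so the null model stands
  expect_warning(stepwise_aic(d, candidates = "flat"), "no candidate")
})
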