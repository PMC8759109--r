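# Internal validation: absolute risk prediction, time-dependent
# discrimination (cumulative sensitivity / dynamic specificity), calibration
# slope, threshold operating characteristics, bootstrap optimism correction.

# reverse Kaplan-Meier of the censoring distribution; returns a function
# G(t) (right-continuous) with optional left limits G(t-)
censoring_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- fit$time
  ss <- fit$surv
  function(t, left = FALSE) {
    pos <- if (left) findInterval(t, tt, left.open = TRUE) else
      findInterval(t, tt)
    ifelse(pos == 0, 1, ss[pmax(pos, 1L)])
  }
}

#' Absolute risk of an event by a horizon
#'
#' `risk = 1 - S0(h)^exp(lp - lp_mean)` with `S0` from the stored Breslow
#' baseline (centered at the training-mean linear predictor).
#'
#' @param fit A fitted `cox_fit` / `decay_cox_fit`.
#' @param newdata Covariate rows (decay indicator and lag columns included
#'   where the model has decaying effects).
#' @param horizon Months; must not exceed the last observed event time.
#' @return Numeric vector of event probabilities.
#' @export
predicted_risk <- function(fit, newdata, horizon) {
  stopifnot(inherits(fit, "cox_fit"), length(horizon) == 1L, horizon >= 0)
  if (horizon == 0) return(rep(0, nrow(newdata)))
  bh <- fit$baseline
  if (horizon > max(bh$time)) {
    stop("horizon ", horizon, " exceeds the last event time; maximum usable ",
         "horizon is ", signif(max(bh$time), 6))
  }
  lp <- cox_fit_lp(fit, newdata)
  H0 <- c(0, bh$cumhaz)[findInterval(horizon, bh$time) + 1L]
  1 - exp(-H0 * exp(lp - fit$lp_mean))
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Cases are subjects with an observed event by the horizon (cumulative
#' sensitivity); controls are subjects still event-free beyond it (dynamic
#' specificity).  Censoring is handled with inverse-probability-of-censoring
#' weights from the reverse Kaplan-Meier of the censoring distribution.  The
#' confidence interval uses the influence-function (two-sample U-statistic
#' projection) variance of the weighted AUC.
#'
#' @param risk Risk scores (any monotone score works).
#' @param time,event Follow-up and event indicator.
#' @param horizon Evaluation horizon (same unit as `time`).
#' @param level Confidence level.
#' @return List with `auc`, `se`, `ci`, `n_cases`, `n_controls`.
#' @export
cumulative_dynamic_auc <- function(risk, time, event, horizon, level = 0.95) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  case <- time <= horizon & event == 1
  ctrl <- time > horizon
  if (!any(case) || !any(ctrl)) {
    stop("AUC undefined at horizon ", horizon, ": ",
         sum(case), " cases and ", sum(ctrl), " controls")
  }
  G <- censoring_km(time, event)
  w <- numeric(length(risk))
  w[case] <- 1 / G(time[case], left = TRUE)
  w[ctrl] <- 1 / G(horizon)
  bad <- (case | ctrl) & (!is.finite(w) | w <= 0)
  if (any(bad)) {
    warning(sum(bad), " subject(s) dropped: censoring survival estimate 0")
    case <- case & !bad
    ctrl <- ctrl & !bad
  }
  o <- order(risk)
  r <- risk[o]
  wc <- ifelse(case, w, 0)[o]
  wn <- ifelse(ctrl, w, 0)[o]
  grp <- cumsum(c(TRUE, r[-1L] != r[-length(r)]))   # unique-risk groups
  cg <- as.vector(rowsum(wc, grp))
  ng <- as.vector(rowsum(wn, grp))
  below <- cumsum(ng) - ng
  W1 <- sum(cg)
  W0 <- sum(ng)
  num <- sum(cg * (below + 0.5 * ng))
  auc <- num / (W1 * W0)
  # per-subject placement values for the projection variance
  qg <- (below + 0.5 * ng) / W0                      # case beats random ctrl
  above_c <- rev(cumsum(rev(cg))) - cg
  pg <- (above_c + 0.5 * cg) / W1                    # ctrl loses to random case
  qi <- qg[grp]
  pi_ <- pg[grp]
  v <- sum((wc * (qi - auc))^2) / W1^2 + sum((wn * (pi_ - auc))^2) / W0^2
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       ci = c(max(0, auc - z * se), min(1, auc + z * se)),
       n_cases = sum(case), n_controls = sum(ctrl))
}

#' Calibration slope of a linear predictor on evaluation data
#'
#' The slope is the coefficient of the (fixed) linear predictor refitted as
#' the sole covariate of a Cox model on the evaluation data.  On the
#' training data of a converged fit the slope is 1 by the score equation;
#' slopes below 1 on fresh data indicate overfitting.
#'
#' @param lp Linear predictors computed from a previously fitted model.
#' @param time,event Follow-up and event indicator of the evaluation data.
#' @param ties Tie correction.
#' @return List with `slope` and `se`.
#' @export
calibration_slope <- function(lp, time, event, ties = "efron") {
  if (stats::sd(lp) == 0) stop("linear predictor has zero variance")
  d <- data.frame(.lp = lp, time = time, event = event)
  fit <- fit_linear_cox(d, ".lp", ties = ties, tol = 1e-10)
  list(slope = unname(fit$coefficients), se = unname(fit$se))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param x Successes; @param n Trials; @param level Confidence level.
#' @return c(lower, upper); the closed Beta-quantile form.
#' @export
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity, specificity and PPV at a predicted-risk threshold
#'
#' Subjects are test-positive when predicted risk >= `threshold`.
#' Outcome-positive subjects have an observed event by the horizon;
#' outcome-negative subjects are followed beyond it event-free.  Subjects
#' censored before the horizon without an event are excluded from
#' classification (default) or, with `ipcw = TRUE`, all subjects are kept
#' and classification counts are weighted by inverse censoring
#' probabilities (CIs then use Kish effective sample sizes and are
#' approximate).
#'
#' @inheritParams cumulative_dynamic_auc
#' @param threshold Risk threshold in (0, 1).
#' @param ipcw Use the inverse-probability-of-censoring-weighted variant.
#' @param level Confidence level for the exact intervals.
#' @return Data frame with one row per metric: estimate, exact CI, and the
#'   effective numerator/denominator.
#' @export
threshold_metrics <- function(risk, time, event, horizon, threshold,
                              ipcw = FALSE, level = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  pos <- time <= horizon & event == 1
  neg <- !pos & time >= horizon
  flag <- risk >= threshold
  if (!ipcw) {
    keep <- pos | neg
    tp <- sum(pos & flag)
    fn <- sum(pos & !flag)
    tn <- sum(neg & !flag)
    fp <- sum(neg & flag)
  } else {
    G <- censoring_km(time, event)
    w <- numeric(length(risk))
    w[pos] <- 1 / G(time[pos], left = TRUE)
    w[neg] <- 1 / G(horizon)
    tp <- sum(w[pos & flag])
    fn <- sum(w[pos & !flag])
    tn <- sum(w[neg & !flag])
    fp <- sum(w[neg & flag])
  }
  one <- function(x, n, metric) {
    if (n <= 0) {
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_, x = x, n = n))
    }
    if (ipcw) {   # Kish effective size for the weighted variant
      x <- round(x)
      n <- round(n)
      x <- min(x, n)
    }
    ci <- clopper_pearson(x, n, level)
    data.frame(metric = metric, estimate = x / n, lower = ci[["lower"]],
               upper = ci[["upper"]], x = x, n = n)
  }
  out <- rbind(one(tp, tp + fn, "sensitivity"),
               one(tn, tn + fp, "specificity"),
               one(tp, tp + fp, "ppv"))
  out$threshold <- threshold
  out$horizon <- horizon
  out
}

#' Bootstrap optimism correction of performance metrics
#'
#' Harrell's algorithm: for each bootstrap resample, the entire modeling
#' pipeline is rerun, each metric is evaluated on the resample (apparent)
#' and on the original data (test), and the mean apparent-minus-test gap is
#' subtracted from the full-data apparent value.  Replicate seeds derive
#' from the master seed by fixed offsets, so results are reproducible.
#'
#' @param data The full analysis data frame.
#' @param pipeline Function `data -> fitted model` embodying the complete
#'   procedure (screening, stepwise selection, decay fitting).  For a fast
#'   approximation it may refit coefficients only; report it as such.
#' @param metrics Named list of functions `(fit, data) -> numeric scalar`.
#' @param B Number of bootstrap replicates (design default 200, the midpoint
#'   of the 100-300 range the method is normally run with).
#' @param seed Master seed.
#' @return Data frame with apparent, optimism, corrected value, and a
#'   percentile CI over replicates for each metric; failed replicates are
#'   dropped with a logged reason (more than 10% failing is an error).
#' @export
optimism_correct <- function(data, pipeline, metrics, B = 200L, seed = 1L) {
  stopifnot(is.function(pipeline), length(metrics) >= 1L,
            !is.null(names(metrics)))
  full_fit <- pipeline(data)
  apparent <- vapply(metrics, function(f) f(full_fit, data), numeric(1))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  opt <- matrix(NA_real_, B, length(metrics),
                dimnames = list(NULL, names(metrics)))
  failures <- character(0)
  n <- nrow(data)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    res <- tryCatch({
      fb <- pipeline(boot)
      app_b <- vapply(metrics, function(f) f(fb, boot), numeric(1))
      test_b <- vapply(metrics, function(f) f(fb, data), numeric(1))
      app_b - test_b
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", b,
                                      conditionMessage(res)))
    } else {
      opt[b, ] <- res
    }
  }
  used <- !is.na(opt[, 1L])
  if (sum(!used) > 0.10 * B) {
    stop("more than 10% of bootstrap replicates failed (",
         sum(!used), "/", B, "); first failure: ", failures[1L])
  }
  optimism <- colMeans(opt[used, , drop = FALSE])
  corr_b <- sweep(-opt[used, , drop = FALSE], 2L, apparent, `+`)
  ci <- apply(corr_b, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(metric = names(metrics), apparent = apparent,
                    optimism = optimism, corrected = apparent - optimism,
                    ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                    B_used = sum(used), row.names = NULL)
  attr(out, "failures") <- failures
  out
}

#' Full internal-validation report for one cohort
#'
#' Computes, per horizon: apparent and optimism-corrected cumulative/dynamic
#' c-statistic and calibration slope; per threshold: sensitivity,
#' specificity and PPV with exact CIs.
#'
#' @param data Analysis data frame (`time`, `event`, covariates).
#' @param pipeline Function `data -> fit`, the full modeling procedure.
#' @param horizons Months at which discrimination/calibration are assessed.
#' @param thresholds Predicted-risk thresholds for operating characteristics.
#' @param B,seed Bootstrap settings for [optimism_correct()].
#' @param ipcw_thresholds Also compute the IPCW variant of the threshold
#'   table.
#' @return A `validation_report` list with elements `performance`,
#'   `thresholds`, and the settings used.
#' @export
validate_model <- function(data, pipeline, horizons = c(12, 36, 60),
                           thresholds = c(0.005, 0.01, 0.02), B = 200L,
                           seed = 1L, ipcw_thresholds = FALSE) {
  fit <- pipeline(data)
  metrics <- list()
  for (h in horizons) {
    local({
      hh <- h
      metrics[[paste0("c_", hh, "m")]] <<- function(f, d) {
        cumulative_dynamic_auc(predicted_risk(f, d, hh), d$time, d$event,
                               hh)$auc
      }
    })
  }
  metrics[["calibration_slope"]] <- function(f, d) {
    calibration_slope(cox_fit_lp(f, d), d$time, d$event, ties = f$ties)$slope
  }
  perf <- optimism_correct(data, pipeline, metrics, B = B, seed = seed)
  thr <- list()
  for (h in horizons) {
    risk <- predicted_risk(fit, data, h)
    for (th in thresholds) {
      thr[[length(thr) + 1L]] <- threshold_metrics(risk, data$time,
                                                   data$event, h, th)
      if (ipcw_thresholds) {
        tt <- threshold_metrics(risk, data$time, data$event, h, th,
                                ipcw = TRUE)
        tt$metric <- paste0(tt$metric, "_ipcw")
        thr[[length(thr) + 1L]] <- tt
      }
    }
  }
  out <- list(fit = fit, performance = perf,
              thresholds = do.call(rbind, thr),
              horizons = horizons, B = B, seed = seed)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Internal validation (B =", x$B, ", seed =", x$seed, ")\n")
  cat("Apparent and optimism-corrected performance:\n")
  print(transform(x$performance,
                  apparent = signif(apparent, 4),
                  optimism = signif(optimism, 4),
                  corrected = signif(corrected, 4),
                  ci_lower = signif(ci_lower, 4),
                  ci_upper = signif(ci_upper, 4)))
  cat("\nOperating characteristics at predicted-risk thresholds:\n")
  tp <- x$thresholds
  tp$estimate <- signif(tp$estimate, 4)
  print(tp[, c("horizon", "threshold", "metric", "estimate", "lower",
               "upper")])
  invisible(x)
}
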