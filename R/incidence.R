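# Descriptive outputs: reverse Kaplan-Meier follow-up and age-standardized
# cumulative incidence.

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Kaplan-Meier estimate with the censoring indicator as the "event"; the
#' median of that curve summarizes potential follow-up.
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = event); censoring is `1 - event`.
#' @return A list with `median` (months; `NA` when not reached), `reached`,
#'   and `max_time`.  Printed as `"> max"` when the median is not reached.
#' @export
reverse_km_median_followup <- function(time, event) {
  if (!any(event == 0)) {
    out <- list(median = NA_real_, reached = FALSE, max_time = max(time))
  } else {
    fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
    out <- list(median = med, reached = !is.na(med), max_time = max(time))
  }
  class(out) <- "reverse_km_median"
  out
}

#' @export
print.reverse_km_median <- function(x, ...) {
  if (x$reached) {
    cat("median follow-up (reverse KM):", signif(x$median, 5), "months\n")
  } else {
    cat("median follow-up (reverse KM): >", signif(x$max_time, 5),
        "months (not reached)\n")
  }
  invisible(x)
}

#' Age-standardized cumulative incidence
#'
#' Fits a Cox model with age as the sole covariate and reports the
#' model-based cumulative incidence for a subject of the standard age:
#' `1 - exp(-H0(tau) * exp(beta * (standard_age - mean age)))`.  Confidence
#' intervals are delta-method on the log cumulative hazard, combining the
#' Poisson-type variance of the baseline increments with the variance of the
#' age coefficient.
#'
#' @param data Data frame with `age`, `time` (months), `event`.
#' @param eval_months Evaluation times.
#' @param standard_age Reference age (default 60).
#' @param level Confidence level.
#' @return An `incidence_curve` data frame: `months`, `incidence`, `lower`,
#'   `upper`, plus attributes `standard_age` and `beta_age`.
#' @export
age_standardized_cuminc <- function(data, eval_months = c(12, 24, 36, 48, 60),
                                    standard_age = 60, level = 0.95) {
  if (!any(data$event == 1)) stop("no events: cumulative incidence undefined")
  fit <- fit_linear_cox(data, "age")
  beta <- unname(fit$coefficients)
  vb <- unname(fit$var[1L, 1L])
  abar <- mean(data$age)
  shift <- exp(beta * (standard_age - abar))

  # risk-set sums at event times for the variance pieces
  core <- cox_pl_core(fit$lp, data$time, data$event, ties = fit$ties,
                      X = fit$design$X, want_derivs = TRUE)
  bh <- fit$baseline
  # reconstruct S0 and S1/S0 per event time (centered scale)
  ord <- order(data$time)
  t_s <- data$time[ord]
  d_s <- data$event[ord]
  e_s <- exp(fit$lp[ord] - mean(fit$lp))
  x_s <- data$age[ord]
  ue <- bh$time
  first <- match(ue, t_s)
  S0 <- revcumsum(e_s)[first]
  S1 <- revcumsum(e_s * x_s)[first]
  dk <- bh$hazard * S0
  z <- stats::qnorm(1 - (1 - level) / 2)

  res <- lapply(eval_months, function(tau) {
    inwin <- ue <= tau
    H0 <- sum(bh$hazard[inwin])
    if (H0 == 0) {
      return(data.frame(months = tau, incidence = 0, lower = 0, upper = 0))
    }
    H <- H0 * shift
    v_pois <- sum(dk[inwin] / S0[inwin]^2) * shift^2
    # d H / d beta: the standardization shift and the baseline both move
    dHdb <- H * (standard_age - abar) -
      shift * sum(dk[inwin] * (S1[inwin] / S0[inwin] - abar) / S0[inwin])
    v <- v_pois + dHdb^2 * vb
    se_log <- sqrt(v) / H
    lo <- H * exp(-z * se_log)
    hi <- H * exp(z * se_log)
    data.frame(months = tau, incidence = 1 - exp(-H),
               lower = 1 - exp(-lo), upper = 1 - exp(-hi))
  })
  out <- do.call(rbind, res)
  attr(out, "standard_age") <- standard_age
  attr(out, "beta_age") <- beta
  class(out) <- c("incidence_curve", "data.frame")
  out
}

#' Age-standardized incidence curves per cohort
#'
#' Convenience wrapper producing one curve per cohort (and optionally per
#' sex) from a stacked analysis dataset.
#'
#' @param dataset An `analysis_dataset` (needs `cohort`, `age`, `time`,
#'   `event`; `sex` if `by_sex`).
#' @inheritParams age_standardized_cuminc
#' @param by_sex Split by sex as well.
#' @return A data frame with columns `cohort` (, `sex`), `months`,
#'   `incidence`, `lower`, `upper`.
#' @export
cohort_incidence <- function(dataset, eval_months = c(12, 24, 36, 48, 60),
                             standard_age = 60, by_sex = FALSE) {
  splits <- if (by_sex) split(dataset, list(dataset$cohort, dataset$sex),
                              drop = TRUE)
  else split(dataset, dataset$cohort)
  out <- lapply(names(splits), function(nm) {
    cc <- tryCatch(
      age_standardized_cuminc(splits[[nm]], eval_months, standard_age),
      error = function(e) NULL)
    if (is.null(cc)) return(NULL)
    cbind(group = nm, as.data.frame(cc))
  })
  do.call(rbind, out)
}
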