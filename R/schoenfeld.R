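# Proportional-hazards diagnostics via scaled Schoenfeld residuals.

#' Scaled Schoenfeld residual test for proportional hazards
#'
#' Tests each covariate (and globally) for a time trend in its scaled
#' Schoenfeld residuals: a score test for zero slope of the residuals
#' against a transform of event time, computed by [survival::cox.zph()] on a
#' model frozen at the fitted coefficients.  For models with decaying
#' effects the working columns `I * exp(-beta2 * t)` at the solution are
#' treated as fixed covariates.
#'
#' @param fit A `cox_fit` or `decay_cox_fit` object.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return A data frame with columns `covariate`, `chisq`, `df`, `p`
#'   (the last row is the global test).  The raw `cox.zph` object is
#'   attached as attribute `"zph"`.
#' @export
schoenfeld_ph_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$nevent < 3L) stop("at least 3 events are required for the test")
  X <- fit$design$X
  cf <- fit$coefficients[seq_len(ncol(X))]
  if (inherits(fit, "decay_cox_fit")) {
    X <- cbind(X, fit$zdata)
    cf <- c(cf, vapply(fit$decay, function(d) d$beta1, numeric(1)))
  }
  if (ncol(X) == 0L) stop("model has no covariates to test")
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X), unique = TRUE)
  covs <- names(df)
  df$.time <- fit$y$time
  df$.status <- fit$y$status
  fml <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(covs, collapse = " + ")))
  frozen <- survival::coxph(fml, data = df, init = unname(cf),
                            ties = fit$ties,
                            control = survival::coxph.control(iter.max = 0))
  zp <- survival::cox.zph(frozen, transform = transform, global = TRUE)
  tab <- as.data.frame(zp$table)
  out <- data.frame(covariate = rownames(tab), chisq = tab$chisq,
                    df = tab$df, p = tab$p, row.names = NULL)
  attr(out, "zph") <- zp
  out
}
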