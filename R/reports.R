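# Delimited-text outputs for cohort tables and fitted-model reports.

#' Write analysis tables per cohort and sex
#'
#' One comma-separated file per cohort x sex combination plus, when given,
#' an exclusions report in YAML.
#'
#' @param dataset An `analysis_dataset` (or the list returned by
#'   [build_analysis_dataset()], whose exclusion report is then included).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_analysis_tables <- function(dataset, dir) {
  report <- NULL
  if (is.list(dataset) && !is.data.frame(dataset) && !is.null(dataset$data)) {
    report <- dataset$exclusion_report
    dataset <- dataset$data
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in unique(dataset$cohort)) {
    for (s in unique(dataset$sex)) {
      sub <- dataset[dataset$cohort == k & dataset$sex == s, , drop = FALSE]
      if (!nrow(sub)) next
      p <- file.path(dir, sprintf("analysis_%s_%s.csv", k, s))
      data.table::fwrite(sub, p, dateTimeAs = "ISO")
      paths <- c(paths, p)
    }
  }
  if (!is.null(report)) {
    p <- file.path(dir, "exclusions.yaml")
    yaml::write_yaml(lapply(seq_len(nrow(report)), function(i)
      as.list(report[i, ])), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a structured text report for a fitted model
#'
#' Coefficients with standard errors, hazard ratios of decaying effects at
#' lags 0 and 36 months, log partial likelihood, AIC, and the convergence
#' record, in YAML.
#'
#' @param fit A `cox_fit` / `decay_cox_fit`.
#' @param path Output file.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "cox_fit"))
  rep_ <- list(
    ties = fit$ties,
    n = fit$n, events = fit$nevent,
    log_partial_likelihood = fit$loglik,
    aic = fit$aic,
    n_parameters = fit$df,
    converged = fit$converged,
    iterations = fit$iter,
    coefficients = lapply(seq_along(fit$coefficients), function(i) list(
      term = names(fit$coefficients)[i],
      estimate = unname(fit$coefficients[i]),
      se = if (length(fit$se) >= i) unname(fit$se[i]) else NA_real_))
  )
  if (!is.null(fit$decay)) {
    rep_$decay_effects <- lapply(names(fit$decay), function(nm) {
      de <- fit$decay[[nm]]
      hr <- hr_at_lag(de, c(0, 36))
      list(term = nm, beta1 = de$beta1, beta2 = de$beta2,
           hr_current = hr$hr[1],
           hr_current_ci = c(hr$lower[1], hr$upper[1]),
           hr_36m = hr$hr[2],
           hr_36m_ci = c(hr$lower[2], hr$upper[2]))
    })
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(rep_, path)
  invisible(path)
}
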