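# Newton-Raphson fitting of linear Cox proportional hazards models on top of
# cox_pl_core().  Used directly for conventional covariates and as the inner
# solver of the iterative-linearization scheme for decaying effects.

# Build a design matrix (no intercept) from term names; factors expand to
# dummy blocks.  Returns the matrix plus bookkeeping needed to rebuild it on
# new data.
build_design <- function(data, covariates) {
  if (length(covariates) == 0L) {
    return(list(X = matrix(numeric(0), nrow(data), 0L), terms = NULL,
                xlevels = NULL, assign = integer(0), labels = character(0)))
  }
  f <- stats::reformulate(covariates)
  mf <- stats::model.frame(f, data, na.action = stats::na.fail)
  tt <- stats::terms(mf)
  mm <- stats::model.matrix(tt, mf)
  asg <- attr(mm, "assign")
  keep <- asg != 0L
  list(X = mm[, keep, drop = FALSE], terms = tt,
       xlevels = stats::.getXlevels(tt, mf),
       assign = asg[keep], labels = attr(tt, "term.labels"))
}

rebuild_design <- function(fit, newdata) {
  if (is.null(fit$design$terms)) {
    return(matrix(numeric(0), nrow(newdata), 0L))
  }
  tt <- stats::delete.response(fit$design$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail,
                           xlev = fit$design$xlevels)
  mm <- stats::model.matrix(tt, mf)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

check_nondegenerate <- function(X) {
  if (ncol(X) == 0L) return(invisible(NULL))
  v <- apply(X, 2L, function(z) diff(range(z)))
  if (any(v == 0)) {
    stop("covariate(s) with zero variance (degenerate): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  }
  invisible(NULL)
}

# Core Newton-Raphson maximizer of the log partial likelihood.
newton_cox <- function(X, time, status, ties = "efron", init = NULL,
                       tol = 1e-8, max_iter = 50L, offset = NULL,
                       diverge_limit = 20) {
  p <- ncol(X)
  beta <- if (is.null(init)) numeric(p) else init
  off <- if (is.null(offset)) 0 else offset
  eta <- off + drop(X %*% beta)
  core <- cox_pl_core(eta, time, status, X, ties = ties, want_derivs = TRUE)
  ll <- core$loglik
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(core$info, core$score), error = function(e) {
      solve(core$info + diag(1e-9, p), core$score)
    })
    if (max(abs(step)) < 1e-8) {   # Newton decrement at the numerical floor
      converged <- TRUE
      break
    }
    frac <- 1
    halvings <- 0L
    repeat {
      cand <- beta + frac * step
      eta <- off + drop(X %*% cand)
      cand_core <- cox_pl_core(eta, time, status, X, ties = ties,
                               want_derivs = TRUE)
      if (cand_core$loglik >= ll - 1e-12 || halvings >= 10L) break
      frac <- frac / 2
      halvings <- halvings + 1L
    }
    rel <- abs(cand_core$loglik - ll) / (abs(ll) + 1e-4)
    beta <- cand
    ll <- cand_core$loglik
    core <- cand_core
    if (any(abs(beta) > diverge_limit)) {
      j <- which.max(abs(beta))
      stop("coefficient for '", colnames(X)[j],
           "' diverged (|beta| > ", diverge_limit,
           "): monotone likelihood / perfect separation suspected")
    }
    if (max(abs(core$score)) < tol && rel < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations (score norm ", signif(max(abs(core$score)), 3), ")")
  }
  list(beta = beta, loglik = ll, score = core$score, info = core$info,
       iter = iter, converged = converged)
}

#' Fit a Cox proportional hazards model with linear covariate effects
#'
#' Newton-Raphson maximization of the Efron- or Breslow-corrected log partial
#' likelihood with step-halving.  Standard errors come from the inverse
#' observed information; the baseline cumulative hazard is the Breslow
#' estimator at the maximum, centered at the training-mean linear predictor.
#'
#' @param data A data frame with one row per subject.
#' @param covariates Character vector of covariate (term) names; factors are
#'   expanded to dummy blocks.  May be empty for a null model.
#' @param time,event Names of the follow-up time and event indicator columns.
#' @param ties Tie correction, `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance: maximum absolute score component and
#'   relative log-likelihood change must both fall below `tol`.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit` with elements `coefficients`, `se`,
#'   `var`, `loglik`, `loglik_null`, `aic`, `df`, `baseline` (Breslow
#'   cumulative hazard step function), `lp` (training linear predictors),
#'   `lp_mean`, `n`, `nevent`, `iter`, `converged`.
#' @export
fit_linear_cox <- function(data, covariates, time = "time", event = "event",
                           ties = "efron", tol = 1e-8, max_iter = 50L) {
  tt <- data[[time]]
  dd <- data[[event]]
  if (is.null(tt) || is.null(dd)) stop("time/event columns not found")
  if (sum(dd == 1) < 1L) stop("at least one event is required")
  des <- build_design(data, covariates)
  check_nondegenerate(des$X)
  p <- ncol(des$X)
  if (p == 0L) {
    core <- cox_pl_core(rep(0, nrow(data)), tt, dd, ties = ties,
                        want_resid = TRUE)
    fit <- list(beta = numeric(0), loglik = core$loglik, score = numeric(0),
                info = matrix(0, 0, 0), iter = 0L, converged = TRUE)
    ll0 <- core$loglik
    lp <- rep(0, nrow(data))
  } else {
    fit <- newton_cox(des$X, tt, dd, ties = ties, tol = tol,
                      max_iter = max_iter)
    ll0 <- cox_pl_core(rep(0, nrow(data)), tt, dd, ties = ties,
                       want_derivs = FALSE)$loglik
    lp <- drop(des$X %*% fit$beta)
    core <- cox_pl_core(lp, tt, dd, ties = ties, want_resid = TRUE)
  }
  v <- if (p > 0L) solve(fit$info) else matrix(0, 0, 0)
  out <- list(
    coefficients = stats::setNames(fit$beta, colnames(des$X)),
    var = v,
    se = if (p > 0L) sqrt(diag(v)) else numeric(0),
    loglik = fit$loglik, loglik_null = ll0,
    df = p, aic = -2 * fit$loglik + 2 * p,
    baseline = core$baseline, lp = lp, lp_mean = mean(lp),
    resid = core$resid,
    n = nrow(data), nevent = sum(dd == 1),
    iter = fit$iter, converged = fit$converged,
    score = fit$score, info = fit$info,
    ties = ties, covariates = covariates, design = des,
    time_col = time, event_col = event,
    y = list(time = tt, status = dd),
    decay = NULL
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (", x$ties, " ties)\n", sep = "")
  cat("  n = ", x$n, ", events = ", x$nevent,
      ", log PL = ", format(x$loglik, digits = 7),
      ", AIC = ", format(x$aic, digits = 7), "\n", sep = "")
  if (length(x$coefficients)) {
    tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                      se = x$se, z = x$coefficients / x$se,
                      check.names = FALSE)
    print(signif(tab, 4))
  }
  if (!is.null(x$decay)) {
    cat("Decaying effects: log HR(t) = beta1 * exp(-beta2 * t)\n")
    for (nm in names(x$decay)) {
      de <- x$decay[[nm]]
      cat(sprintf("  %s: beta1 = %.4f (HR0 = %.3f), beta2 = %.5f /month\n",
                  nm, de$beta1, exp(de$beta1), de$beta2))
    }
  }
  invisible(x)
}

#' Linear predictor or absolute risk from a fitted model
#'
#' @param object A `cox_fit` (or `decay_cox_fit`) object.
#' @param newdata Data frame holding the model's covariate columns (and, for
#'   decay effects, their lag columns).
#' @param type `"lp"` for the linear predictor or `"risk"` for absolute risk
#'   by `horizon` (see [predicted_risk()]).
#' @param horizon Risk horizon in the time unit of the training data
#'   (required for `type = "risk"`).
#' @param ... Unused.
#' @export
predict.cox_fit <- function(object, newdata, type = c("lp", "risk"),
                            horizon = NULL, ...) {
  type <- match.arg(type)
  lp <- cox_fit_lp(object, newdata)
  if (type == "lp") return(lp)
  if (is.null(horizon)) stop("'horizon' is required for type = 'risk'")
  predicted_risk(object, newdata, horizon)
}

# linear predictor on new data (handles decay terms when present)
cox_fit_lp <- function(fit, newdata) {
  X <- rebuild_design(fit, newdata)
  lin_names <- colnames(X)
  lp <- if (ncol(X)) drop(X %*% fit$coefficients[lin_names]) else
    rep(0, nrow(newdata))
  if (!is.null(fit$decay)) {
    for (nm in names(fit$decay)) {
      de <- fit$decay[[nm]]
      I <- newdata[[nm]]
      tl <- newdata[[paste0(nm, fit$lag_suffix)]]
      if (is.null(I)) stop("decay indicator column '", nm, "' not in newdata")
      tl[is.na(tl) | I == 0] <- 0
      lp <- lp + I * de$beta1 * exp(-de$beta2 * tl)
    }
  }
  unname(lp)
}
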