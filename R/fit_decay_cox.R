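# Cox models with exponentially decaying log hazard ratios.
#
# A binary predictor I recorded `t` months before cohort entry contributes
# log HR(t) = beta1 * exp(-beta2 * t) to the log hazard, held fixed at its
# index-date value.  (beta1, beta2) are estimated by iterative linearization:
# at each outer step, given the current beta2, two working covariates are
# formed per decay term,
#   z1 = I * exp(-beta2 * t)                (carrier of beta1)
#   z2 = -beta1 * I * t * exp(-beta2 * t)   (d LP / d beta2)
# a linear Cox model is fitted in (linear covariates, z1, z2), and
# beta1 <- coef(z1), beta2 <- beta2 + coef(z2).  A converged fixed point is a
# stationary point of the full nonlinear partial likelihood because at the
# fixed point the working design equals the Jacobian of the nonlinear linear
# predictor.

#' Exponentially decaying covariate effect
#'
#' Defines log HR(t) = `beta1` * exp(-`beta2` * t) for a binary predictor
#' whose first record occurred `t` months before the index date.
#'
#' @param beta1 Log hazard ratio at lag 0 (the "current" effect).
#' @param beta2 Decay rate per month; 0 gives a constant effect.
#' @param vcov Optional 2x2 covariance matrix of (beta1, beta2).
#' @return An object of class `decay_effect`.
#' @export
decay_effect <- function(beta1, beta2, vcov = NULL) {
  stopifnot(is.finite(beta1), is.finite(beta2))
  structure(list(beta1 = beta1, beta2 = beta2, vcov = vcov),
            class = "decay_effect")
}

#' Constant (linear) covariate effect for the simulator's ground truth
#'
#' @param beta Log hazard ratio per unit of the covariate.
#' @param center Value subtracted from the covariate before multiplying, so
#'   that a "typical" subject sits at linear predictor 0.
#' @export
linear_effect <- function(beta, center = 0) {
  stopifnot(is.finite(beta), is.finite(center))
  structure(list(beta = beta, center = center), class = "linear_effect")
}

#' @export
print.decay_effect <- function(x, ...) {
  cat(sprintf(
    "decay effect: log HR(t) = %.4f * exp(-%.5f t); HR(0) = %.3f, HR(36) = %.3f\n",
    x$beta1, x$beta2, exp(x$beta1), exp(x$beta1 * exp(-x$beta2 * 36))))
  invisible(x)
}

#' Solve the decay rate from two hazard ratios
#'
#' Given the hazard ratio at lag 0 and at lag `t` months, returns the
#' `beta2` such that `exp(beta1 * exp(-beta2 * t))` equals the lagged value,
#' where `beta1 = log(hr0)`.
#'
#' @param hr0 Hazard ratio at lag 0.
#' @param hr_t Hazard ratio at lag `t`.
#' @param t Lag in months.
#' @export
solve_decay_rate <- function(hr0, hr_t, t) {
  stopifnot(hr0 > 0, hr_t > 0, t > 0)
  log(log(hr0) / log(hr_t)) / t
}

#' Hazard ratio of a decaying effect at a given lag, with delta-method CI
#'
#' HR(t) = exp(beta1 * exp(-beta2 * t)).  The confidence interval uses the
#' delta-method variance of g(beta1, beta2) = beta1 * exp(-beta2 * t) with
#' gradient (exp(-beta2 t), -beta1 t exp(-beta2 t)).
#'
#' @param effect A [decay_effect()] (with `vcov` set if a CI is wanted).
#' @param t Lag in months, `t >= 0`.
#' @param level Confidence level (default 0.95).
#' @return A data frame with columns `t`, `hr`, `lower`, `upper`.
#' @export
hr_at_lag <- function(effect, t, level = 0.95) {
  stopifnot(inherits(effect, "decay_effect"))
  if (any(t < 0)) stop("lag t must be non-negative")
  g <- effect$beta1 * exp(-effect$beta2 * t)
  if (!is.null(effect$vcov)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- vapply(t, function(ti) {
      gr <- c(exp(-effect$beta2 * ti),
              -effect$beta1 * ti * exp(-effect$beta2 * ti))
      sqrt(drop(gr %*% effect$vcov %*% gr))
    }, numeric(1))
    data.frame(t = t, hr = exp(g), lower = exp(g - z * se),
               upper = exp(g + z * se))
  } else {
    data.frame(t = t, hr = exp(g), lower = NA_real_, upper = NA_real_)
  }
}

#' Fit a Cox model with exponentially decaying binary effects
#'
#' Iterative linearization (Gauss-Newton with step-halving on the nonlinear
#' log partial likelihood).  Each decay covariate `nm` requires a 0/1
#' indicator column `nm` and a lag column `paste0(nm, lag_suffix)` giving
#' months from the first record to the index date (ignored where the
#' indicator is 0).  `beta2` is constrained non-negative (decay, not growth)
#' unless `nonneg_beta2 = FALSE`.
#'
#' The final covariance matrix is the inverse observed information of the
#' full nonlinear model at the solution (not of the last linearization), so
#' the variance of `beta2` is not understated.
#'
#' @inheritParams fit_linear_cox
#' @param linear_covs Names of ordinary covariates (possibly empty).
#' @param decay_covs Names of the indicator columns carrying decaying effects.
#' @param lag_suffix Suffix of the lag columns (default `"_lag"`).
#' @param beta2_init Starting decay rates (recycled; default 0).
#' @param nonneg_beta2 Project decay rates to `>= 0` after each update.
#' @param fix_beta2 Keep all decay rates fixed at `beta2_init` (no duration
#'   estimation); with `beta2_init = 0` this reproduces [fit_linear_cox()] on
#'   the plain indicators.
#' @param init Optional warm start: a list with `gamma` (linear
#'   coefficients), `beta1`, and `beta2`, e.g. from a previous fit on
#'   similar data (used by bootstrap refits).
#' @param max_iter Maximum outer linearization iterations.
#' @return A `decay_cox_fit` object (inherits `cox_fit`); the `decay` element
#'   holds one [decay_effect()] per decay covariate, with its 2x2 covariance
#'   block, and `trace` records the outer-iteration path.
#' @export
fit_decay_cox <- function(data, linear_covs, decay_covs, time = "time",
                          event = "event", ties = "efron", lag_suffix = "_lag",
                          tol = 1e-8, max_iter = 100L, beta2_init = 0,
                          nonneg_beta2 = TRUE, fix_beta2 = FALSE,
                          init = NULL) {
  stopifnot(length(decay_covs) >= 1L)
  tt <- data[[time]]
  dd <- data[[event]]
  if (sum(dd == 1) < 1L) stop("at least one event is required")
  n <- nrow(data)
  m <- length(decay_covs)
  des <- build_design(data, linear_covs)
  Xlin <- des$X
  check_nondegenerate(Xlin)
  pl <- ncol(Xlin)

  I <- matrix(0, n, m, dimnames = list(NULL, decay_covs))
  TL <- matrix(0, n, m)
  for (j in seq_len(m)) {
    nm <- decay_covs[j]
    Ij <- data[[nm]]
    lj <- data[[paste0(nm, lag_suffix)]]
    if (is.null(Ij)) stop("decay indicator column '", nm, "' not found")
    if (is.null(lj)) stop("lag column '", paste0(nm, lag_suffix),
                          "' not found for decay covariate '", nm, "'")
    if (all(Ij == 0)) stop("decay covariate '", nm, "' has no positive ",
                           "indicators; cannot estimate its effect")
    lj[Ij == 0] <- 0
    if (any(is.na(lj))) stop("missing lag for positive indicator of '", nm, "'")
    if (any(lj < 0)) stop("negative lag for decay covariate '", nm, "'")
    I[, j] <- Ij
    TL[, j] <- lj
  }

  b2 <- rep_len(beta2_init, m)
  if (nonneg_beta2) b2 <- pmax(b2, 0)

  nl_lp <- function(gam, b1, b2) {
    lp <- if (pl) drop(Xlin %*% gam) else rep(0, n)
    for (j in seq_len(m)) lp <- lp + I[, j] * b1[j] * exp(-b2[j] * TL[, j])
    lp
  }
  nl_ll <- function(gam, b1, b2) {
    cox_pl_core(nl_lp(gam, b1, b2), tt, dd, ties = ties,
                want_derivs = FALSE)$loglik
  }

  if (!is.null(init)) {
    gam <- if (pl) rep_len(init$gamma, pl) else numeric(0)
    b1 <- rep_len(init$beta1, m)
    b2 <- rep_len(init$beta2, m)
    if (nonneg_beta2) b2 <- pmax(b2, 0)
  } else {
    # initialize beta1 (and gamma) with the indicators at the starting beta2
    z1 <- I * exp(-sweep(TL, 2L, b2, `*`))
    colnames(z1) <- paste0(decay_covs, ".z1")
    f0 <- newton_cox(cbind(Xlin, z1), tt, dd, ties = ties, tol = tol)
    gam <- f0$beta[seq_len(pl)]
    b1 <- f0$beta[pl + seq_len(m)]
  }
  ll <- nl_ll(gam, b1, b2)

  trace <- data.frame(iter = 0L, loglik = ll,
                      max_change = NA_real_, step_frac = 1)
  converged <- FALSE
  # Newton decrement of the full nonlinear model: the parameter error
  # implied by one exact Newton step.  Used to accept iterates whose
  # change-based test stalls in a tiny limit cycle around the beta2 >= 0
  # boundary (the max per-iteration change then stops shrinking even
  # though the solution is numerically attained).
  newton_decrement <- function() {
    ee <- exp(-sweep(TL, 2L, b2, `*`))
    Jc <- cbind(Xlin, I * ee, -sweep(I * TL * ee, 2L, b1, `*`))
    core_c <- cox_pl_core(nl_lp(gam, b1, b2), tt, dd, X = Jc, ties = ties,
                          want_derivs = TRUE)
    dec <- tryCatch(solve(core_c$info, core_c$score),
                    error = function(e) rep(Inf, ncol(Jc)))
    free <- rep(TRUE, ncol(Jc))
    if (nonneg_beta2) {    # boundary rates may carry an outward gradient
      free[pl + m + which(b2 <= 0)] <- FALSE
    }
    list(step = dec, size = max(abs(dec[free])))
  }
  # direct Gauss-Newton steps on the joint nonlinear model; drives the
  # remaining parameter error below ~1e-9 once the outer loop is close
  polish <- function() {
    for (k in 1:6) {
      st <- newton_decrement()
      if (!is.finite(st$size) || st$size < 1e-9) break
      g_n <- gam + st$step[seq_len(pl)]
      b1n <- b1 + st$step[pl + seq_len(m)]
      b2n <- b2 + st$step[pl + m + seq_len(m)]
      if (nonneg_beta2) b2n <- pmax(b2n, 0)
      ll_n <- nl_ll(g_n, b1n, b2n)
      if (ll_n < ll - 1e-10) break
      gam <<- g_n; b1 <<- b1n; b2 <<- b2n; ll <<- ll_n
    }
  }
  for (it in seq_len(max_iter)) {
    ee <- exp(-sweep(TL, 2L, b2, `*`))
    z1 <- I * ee
    z2 <- -sweep(I * TL * ee, 2L, b1, `*`)
    colnames(z1) <- paste0(decay_covs, ".z1")
    colnames(z2) <- paste0(decay_covs, ".z2")
    live <- if (fix_beta2) integer(0) else
      which(abs(b1) > 1e-12)              # z2 is identically 0 when beta1 = 0
    Xw <- cbind(Xlin, z1, z2[, live, drop = FALSE])
    fw <- newton_cox(Xw, tt, dd, ties = ties, tol = tol,
                     init = c(gam, b1, rep(0, length(live))))
    db2 <- numeric(m)
    db2[live] <- fw$beta[pl + m + seq_along(live)]
    # KKT at the boundary: a rate pinned at 0 whose step points outside the
    # feasible region is frozen (its working column dropped) and the
    # remaining parameters refitted, so the iteration has a true fixed point
    if (nonneg_beta2) {
      frozen <- which(b2 <= 0 & db2 < 0)
      live2 <- setdiff(live, frozen)
      if (length(frozen) && !identical(live2, live)) {
        Xw <- cbind(Xlin, z1, z2[, live2, drop = FALSE])
        fw <- newton_cox(Xw, tt, dd, ties = ties, tol = tol,
                         init = c(gam, b1, rep(0, length(live2))))
        db2 <- numeric(m)
        db2[live2] <- fw$beta[pl + m + seq_along(live2)]
      }
    }
    gam_p <- fw$beta[seq_len(pl)]
    b1_p <- fw$beta[pl + seq_len(m)]
    b2_p <- b2 + db2
    if (nonneg_beta2) b2_p <- pmax(b2_p, 0)

    # step-halving on the nonlinear objective
    frac <- 1
    halvings <- 0L
    repeat {
      gc_ <- gam + frac * (gam_p - gam)
      b1c <- b1 + frac * (b1_p - b1)
      b2c <- b2 + frac * (b2_p - b2)
      if (nonneg_beta2) b2c <- pmax(b2c, 0)
      ll_c <- nl_ll(gc_, b1c, b2c)
      if (ll_c >= ll - 1e-12 || halvings >= 10L) break
      frac <- frac / 2
      halvings <- halvings + 1L
    }
    chg <- max(abs(c(gc_ - gam, b1c - b1, b2c - b2)))
    gam <- gc_; b1 <- b1c; b2 <- b2c; ll <- ll_c
    trace <- rbind(trace, data.frame(iter = it, loglik = ll,
                                     max_change = chg, step_frac = frac))
    if (chg < tol) {
      converged <- TRUE
      break
    }
    # shortcut for slow linear tails: once iterates are close, a few direct
    # Gauss-Newton steps on the joint model finish faster than the
    # working-column iteration
    if (chg < 1e-2 && (it >= 8L || chg < 1e-4)) {
      polish()
      if (newton_decrement()$size < 1e-8) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    dec <- newton_decrement()$size
    if (dec < 1e-5) {
      polish()
      converged <- TRUE
    } else {
      stop("iterative linearization did not converge in ", max_iter,
           " iterations (last max parameter change ",
           signif(utils::tail(trace$max_change, 1), 3),
           ", Newton decrement ", signif(dec, 3), ")")
    }
  }

  gam <- unname(gam)
  b1 <- unname(b1)
  b2 <- unname(b2)

  # observed information of the full nonlinear model at the solution
  ee <- exp(-sweep(TL, 2L, b2, `*`))
  z1 <- I * ee
  dz2 <- -sweep(I * TL * ee, 2L, b1, `*`)
  colnames(z1) <- decay_covs
  colnames(dz2) <- paste0(decay_covs, ":decay")
  J <- cbind(Xlin, z1, dz2)
  lp <- nl_lp(gam, b1, b2)
  core <- cox_pl_core(lp, tt, dd, X = J, ties = ties, want_derivs = TRUE,
                      want_resid = TRUE)
  info <- core$info
  u <- core$resid
  for (j in seq_len(m)) {
    a <- I[, j] * TL[, j] * ee[, j]              # -d2 LP / (d b1 d b2)
    b <- b1[j] * I[, j] * TL[, j]^2 * ee[, j]    #  d2 LP / d b2^2
    i1 <- pl + j
    i2 <- pl + m + j
    info[i1, i2] <- info[i1, i2] + sum(u * a)
    info[i2, i1] <- info[i1, i2]
    info[i2, i2] <- info[i2, i2] - sum(u * b)
  }
  v <- tryCatch(solve(info), error = function(e) {
    warning("observed information singular at the solution; ",
            "covariance set to NA")
    matrix(NA_real_, nrow(info), ncol(info), dimnames = dimnames(info))
  })

  theta <- c(gam, b1, b2)
  names(theta) <- c(colnames(Xlin), decay_covs,
                    paste0(decay_covs, ":decay"))
  decay <- stats::setNames(vector("list", m), decay_covs)
  for (j in seq_len(m)) {
    idx <- c(pl + j, pl + m + j)
    decay[[decay_covs[j]]] <- decay_effect(b1[j], b2[j],
                                           vcov = v[idx, idx, drop = FALSE])
  }
  npar <- pl + 2L * m
  ll0 <- cox_pl_core(rep(0, n), tt, dd, ties = ties,
                     want_derivs = FALSE)$loglik
  out <- list(
    coefficients = theta,
    var = v, se = sqrt(pmax(diag(v), 0)),
    loglik = ll, loglik_null = ll0,
    df = npar, aic = -2 * ll + 2 * npar,
    baseline = core$baseline, lp = lp, lp_mean = mean(lp),
    resid = u,
    n = n, nevent = sum(dd == 1),
    iter = nrow(trace) - 1L, converged = converged, trace = trace,
    score = core$score, info = info,
    ties = ties, covariates = linear_covs, design = des,
    decay = decay, decay_covs = decay_covs, lag_suffix = lag_suffix,
    zdata = z1,
    time_col = time, event_col = event,
    y = list(time = tt, status = dd)
  )
  class(out) <- c("decay_cox_fit", "cox_fit")
  out
}

#' Extract the decaying effects of a fitted model
#'
#' @param fit A `decay_cox_fit` object.
#' @return Named list of [decay_effect()] objects.
#' @export
decay_effects <- function(fit) {
  if (is.null(fit$decay)) stop("model has no decaying effects")
  fit$decay
}
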