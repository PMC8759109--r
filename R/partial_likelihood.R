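# Cox partial-likelihood engine.
#
# One internal workhorse, cox_pl_core(), computes the log partial likelihood,
# its gradient and observed information with respect to the coefficients of a
# supplied design matrix, per-subject derivatives with respect to the linear
# predictor (generalized martingale residuals), and the Breslow baseline
# cumulative hazard.  Subjects are first collapsed into inter-event-time
# groups (rowsum), so the reverse cumulative risk-set sums run over the
# unique event times rather than over subjects; Efron and Breslow tie
# corrections share the same code path (Breslow is the Efron formula with
# the tie fraction fixed at zero).

revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n <= 1L) return(x)
    apply(x[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

# risk-set sums at each unique event time: grp[i] = number of event times
# <= t_i (0..K); at-risk for event time k means grp >= k.  Returns a K x p
# matrix (or length-K vector) of sums over the risk sets.
riskset_sums <- function(x, grp, K) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  gs <- rowsum(xm, grp)              # rows labeled by sorted unique grp value
  full <- matrix(0, K + 1L, ncol(xm))
  full[as.integer(rownames(gs)) + 1L, ] <- gs
  cs <- revcumsum(full)
  if (is.matrix(x)) cs[-1L, , drop = FALSE] else cs[-1L, 1L]
}

# eta: linear predictor (length n); X: optional design matrix whose coefficient
# derivatives are requested, evaluated at the given eta (score = X' u,
# info = X' W X where W is minus the Hessian of the log partial likelihood in
# eta).  Residuals are dl/deta per subject.
cox_pl_core <- function(eta, time, status, X = NULL,
                        ties = c("efron", "breslow"),
                        want_derivs = !is.null(X), want_resid = FALSE) {
  ties <- match.arg(ties)
  n <- length(time)
  if (length(eta) == 1L) eta <- rep(eta, n)
  stopifnot(length(eta) == n, length(status) == n)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  p <- if (is.null(X)) 0L else ncol(X)

  out <- list(loglik = 0, score = numeric(p),
              info = matrix(0, p, p), resid = numeric(n),
              baseline = data.frame(time = numeric(0), hazard = numeric(0),
                                    cumhaz = numeric(0)),
              lp_mean = mean(eta), nevent = sum(status == 1))
  if (!any(status == 1)) {
    warning("no events in dataset: partial likelihood is identically 0")
    return(out)
  }

  ord <- order(time)
  t_s <- time[ord]
  d_s <- status[ord]
  eta_c <- eta - mean(eta)           # shift-invariant; improves conditioning
  e_s <- exp(eta_c[ord])
  ev <- d_s == 1
  ue <- unique(t_s[ev])              # ascending unique event times
  K <- length(ue)
  grp <- findInterval(t_s, ue)       # at risk for ue[k] iff grp >= k

  gi <- match(t_s[ev], ue)           # event -> event-time group
  dk <- tabulate(gi, nbins = K)
  s0d <- as.vector(rowsum(e_s[ev], gi))
  S0 <- riskset_sums(e_s, grp, K)

  # expansion over Efron tie fractions l/d, l = 0..d-1 (Breslow: fraction 0)
  kid <- rep(seq_len(K), dk)
  lfrac <- if (ties == "efron") {
    unlist(lapply(dk, function(d) (seq_len(d) - 1) / d), use.names = FALSE)
  } else {
    numeric(sum(dk))
  }
  denom <- S0[kid] - lfrac * s0d[kid]

  out$loglik <- sum(eta_c[ord][ev]) - sum(log(denom))

  if (want_derivs && p > 0L) {
    Xs <- X[ord, , drop = FALSE]
    wX <- e_s * Xs
    S1 <- riskset_sums(wX, grp, K)
    s1d <- rowsum(wX[ev, , drop = FALSE], gi)
    comb <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    XX <- Xs[, comb[, 1L], drop = FALSE] * Xs[, comb[, 2L], drop = FALSE]
    wXX <- e_s * XX
    S2 <- riskset_sums(wXX, grp, K)
    s2d <- rowsum(wXX[ev, , drop = FALSE], gi)

    S1e <- S1[kid, , drop = FALSE] - lfrac * s1d[kid, , drop = FALSE]
    S2e <- S2[kid, , drop = FALSE] - lfrac * s2d[kid, , drop = FALSE]
    mu <- S1e / denom
    xev <- colSums(Xs[ev, , drop = FALSE])
    out$score <- xev - colSums(mu)
    ipp <- colSums(S2e / denom) - colSums(mu[, comb[, 1L], drop = FALSE] *
                                            mu[, comb[, 2L], drop = FALSE])
    info <- matrix(0, p, p)
    info[cbind(comb[, 1L], comb[, 2L])] <- ipp
    info[cbind(comb[, 2L], comb[, 1L])] <- ipp
    dimnames(info) <- list(colnames(X), colnames(X))
    out$info <- info
    out$score <- stats::setNames(out$score, colnames(X))
  }

  if (want_resid) {
    A <- as.vector(rowsum(1 / denom, kid))              # sum_l 1/denom_kl
    B <- as.vector(rowsum((1 - lfrac) / denom, kid))    # own-event weight
    cumA <- cumsum(A)
    Ki <- findInterval(t_s, ue)
    haz <- ifelse(Ki > 0, cumA[pmax(Ki, 1L)], 0)
    own <- ev & Ki > 0 & t_s == ue[pmax(Ki, 1L)]
    haz[own] <- haz[own] - A[Ki[own]] + B[Ki[own]]
    r_s <- d_s - e_s * haz
    out$resid[ord] <- r_s
  }

  # Breslow baseline cumulative hazard on the centered linear-predictor scale
  hk <- dk / S0
  out$baseline <- data.frame(time = ue, hazard = hk, cumhaz = cumsum(hk))
  out
}

#' Negative log partial likelihood of a Cox model
#'
#' Evaluates \eqn{-\log PL} for a vector of per-subject linear predictors
#' under the Efron or Breslow tie correction.  The partial likelihood is
#' invariant to adding a constant to all linear predictors.
#'
#' @param lp Numeric vector of linear predictors, one per subject.  For a
#'   model with decaying binary effects this is
#'   \eqn{\sum_j x_j \gamma_j + \sum_m I_m \beta_{1m} e^{-\beta_{2m} t_m}}.
#' @param time Follow-up time (any consistent unit).
#' @param status Event indicator, 1 = event, 0 = censored.
#' @param ties Tie correction, `"efron"` (default) or `"breslow"`.
#' @return A single number, \eqn{-\log PL}.  If the data contain no events
#'   the value is 0 and a warning is emitted.
#' @examples
#' # one event among three subjects at equal risk: -log(1/3)
#' neg_log_partial_likelihood(c(0, 0, 0), c(1, 2, 3), c(1, 0, 0))
#' @export
neg_log_partial_likelihood <- function(lp, time, status, ties = "efron") {
  core <- cox_pl_core(lp, time, status, ties = ties, want_derivs = FALSE)
  -core$loglik
}
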