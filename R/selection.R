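# Stepwise AIC model selection with duration-term constraints.
#
# Stage 1 runs conventional stepwise AIC over linear/categorical/indicator
# terms, with decay-eligible indicators entering as constant effects (their
# decay rate frozen at 0).  Stage 2 frees the decay rate of every retained
# decay-eligible indicator regardless of the AIC change: duration parameters
# accompany their indicator whenever the indicator is in the model.

#' Screen covariate pairs for collinearity
#'
#' For every pair of numeric covariates with `|Pearson r| >= r_threshold`
#' the member with the larger univariate Cox AIC is dropped.  Pairs are
#' processed in decreasing `|r|`; at `r_threshold = 0` exactly one covariate
#' survives per connected correlation component.
#'
#' @inheritParams fit_linear_cox
#' @param r_threshold Absolute-correlation threshold (default 0.8).
#' @return A list with `retained` (covariate names), `dropped` (data frame of
#'   decisions: dropped, kept, r), and `univariate_aic`.
#' @export
correlation_screen <- function(data, covariates, time = "time",
                               event = "event", r_threshold = 0.8,
                               ties = "efron") {
  num <- covariates[vapply(data[covariates], is.numeric, logical(1))]
  keep_nonnum <- setdiff(covariates, num)
  if (length(num) < 2L) {
    return(list(retained = covariates,
                dropped = data.frame(dropped = character(),
                                     kept = character(), r = numeric()),
                univariate_aic = NULL))
  }
  cm <- stats::cor(data[num], use = "pairwise.complete.obs")
  uaic <- vapply(num, function(v) {
    fit_linear_cox(data, v, time = time, event = event, ties = ties)$aic
  }, numeric(1))
  pairs <- which(upper.tri(cm) & abs(cm) >= r_threshold, arr.ind = TRUE)
  dropped <- data.frame(dropped = character(), kept = character(),
                        r = numeric())
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    alive <- stats::setNames(rep(TRUE, length(num)), num)
    for (i in seq_len(nrow(pairs))) {
      a <- num[pairs[i, 1L]]
      b <- num[pairs[i, 2L]]
      if (!alive[a] || !alive[b]) next
      worse <- if (uaic[a] > uaic[b]) a else if (uaic[b] > uaic[a]) b else
        max(a, b)   # deterministic name-based tie-break
      alive[worse] <- FALSE
      dropped <- rbind(dropped,
                       data.frame(dropped = worse,
                                  kept = setdiff(c(a, b), worse),
                                  r = cm[pairs[i, 1L], pairs[i, 2L]]))
    }
    num <- num[alive[num]]
  }
  list(retained = c(num, keep_nonnum), dropped = dropped,
       univariate_aic = uaic)
}

#' Stepwise AIC selection with duration-term constraints
#'
#' Stage 1: starting from the forced-in set, repeatedly applies the single
#' add or drop move that most improves the AIC (candidates evaluated with
#' decay-eligible indicators as constant effects); ties are broken by
#' covariate name, so the result does not depend on input ordering.
#' Stage 2: every retained decay-eligible indicator has its decay rate freed
#' and the model is refitted by [fit_decay_cox()] regardless of the AIC
#' change.
#'
#' @inheritParams fit_linear_cox
#' @param candidates Candidate covariate (term) names.
#' @param forced Covariates kept in every model (e.g. `"age"`).
#' @param decay_eligible Indicator candidates that carry a duration (lag)
#'   column and receive a decay term if retained.
#' @param direction `"both"` (default), `"forward"`, or `"backward"`.
#' @param lag_suffix Suffix of the lag columns.
#' @return A list with `selected` (final term names), `fit` (the final
#'   [fit_linear_cox()] or [fit_decay_cox()] object), `trail` (the per-step
#'   AIC record across both stages), `forced`, and `decay_selected`.
#' @export
stepwise_aic <- function(data, candidates, forced = character(),
                         decay_eligible = character(),
                         direction = c("both", "forward", "backward"),
                         time = "time", event = "event", ties = "efron",
                         lag_suffix = "_lag") {
  direction <- match.arg(direction)
  candidates <- sort(setdiff(candidates, forced))
  current <- if (direction == "backward") sort(c(forced, candidates)) else
    sort(forced)
  fit_terms <- function(terms) {
    fit_linear_cox(data, terms, time = time, event = event, ties = ties)
  }
  cur_fit <- fit_terms(current)
  trail <- data.frame(stage = 1L, step = 0L, action = "start",
                      covariate = "", aic = cur_fit$aic,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    step <- step + 1L
    moves <- list()
    if (direction %in% c("both", "forward")) {
      for (v in sort(setdiff(candidates, current))) {
        moves[[paste0("+", v)]] <- sort(c(current, v))
      }
    }
    if (direction %in% c("both", "backward")) {
      for (v in sort(setdiff(current, forced))) {
        moves[[paste0("-", v)]] <- sort(setdiff(current, v))
      }
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(tm) {
      tryCatch(fit_terms(tm)$aic, error = function(e) Inf)
    }, numeric(1))
    best <- names(aics)[order(aics, names(aics))][1L]   # name tie-break
    if (aics[best] >= cur_fit$aic - 1e-10) break
    current <- moves[[best]]
    cur_fit <- fit_terms(current)
    trail <- rbind(trail, data.frame(stage = 1L, step = step,
                                     action = substr(best, 1L, 1L),
                                     covariate = substring(best, 2L),
                                     aic = cur_fit$aic))
  }
  if (identical(sort(current), sort(forced)) &&
      length(setdiff(candidates, forced))) {
    warning("no candidate improved the AIC over the forced-in model")
  }

  decay_sel <- sort(intersect(decay_eligible, current))
  if (length(decay_sel)) {
    lin <- setdiff(current, decay_sel)
    final <- fit_decay_cox(data, lin, decay_sel, time = time, event = event,
                           ties = ties, lag_suffix = lag_suffix)
    trail <- rbind(trail, data.frame(stage = 2L, step = step,
                                     action = "decay",
                                     covariate = paste(decay_sel,
                                                       collapse = "+"),
                                     aic = final$aic))
  } else {
    final <- cur_fit
  }
  list(selected = current, fit = final, trail = trail, forced = forced,
       decay_selected = decay_sel)
}
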