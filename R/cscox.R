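# Cause-specific Cox regression for a binary group covariate. Events of the
# other cause are recoded as censored; the Breslow partial likelihood for the
# single coefficient is maximised by Newton-Raphson with step-halving. With a
# binary covariate the risk-set sums reduce to counts of at-risk subjects per
# arm, so the score and information have closed forms.

#' Fit a cause-specific Cox model for a binary treatment group
#'
#' Fits the proportional cause-specific-hazards model
#' \eqn{\alpha_{0j}(t \mid Z) = \alpha_{0j}(t) e^{\beta_j Z}} for one cause
#' \eqn{j}, treating events of the other cause as censored. Ties are handled
#' with the Breslow approximation (discrete empirical laws generate many
#' ties by design). Newton-Raphson starts at 0, halves steps whenever the
#' log partial likelihood would decrease, and stops when the absolute score
#' falls below `1e-8` or the step below `1e-10` (at most 50 iterations).
#' The standard error comes from the observed information at the maximum.
#'
#' A partial likelihood without a finite maximiser -- complete separation
#' (all target-cause events in one arm) or, more generally, a score that no
#' longer changes sign over the real line -- is reported as a non-converged
#' fit with `NA` coefficient rather than an error.
#'
#' @param data A [crdata] object with a `group` column containing both arms.
#' @param cause Target cause, 1 or 2.
#' @return An object of class `"cscox"`: a list with `coefficient` (the log
#'   cause-specific hazard ratio), `standard_error`, `wald_ci` (95%),
#'   `p_value` (two-sided Wald), `loglik`, `converged`, `iterations`,
#'   `cause`, `n`, `n_events`.
#' @examples
#' d <- crdata(time = c(1, 2, 3), status = c(1, 1, 1), group = c(0, 1, 0))
#' coef(cscox(d, cause = 1))
#' @export
cscox <- function(data, cause = 1) {
  cause <- match_cause(cause)
  stopifnot(inherits(data, "crdata"))
  if (!"group" %in% names(data)) {
    stop_crsim("dataset has no group column", "validation")
  }
  if (length(unique(data$group)) < 2L) {
    stop_crsim("both groups must be present", "validation")
  }
  fit <- cscox_engine(data$time, data$status, data$group, cause)
  fit$n <- nrow(data)
  class(fit) <- "cscox"
  fit
}

# Aggregates per unique event time: d (events), s1 (events in arm 1),
# y1/y0 (at risk per arm). Inputs need not be sorted.
breslow_tables <- function(time, status, z, cause) {
  ev <- status == cause
  if (!any(ev)) stop_crsim(sprintf("no cause-%d events in the data", cause), "validation")
  ut <- sort(unique(time))
  k <- match(time, ut)
  nb <- length(ut)
  cnt <- tabulate(k, nbins = nb)
  cnt1 <- tabulate(k[z == 1L], nbins = nb)
  y <- length(time) - c(0, cumsum(cnt))[seq_len(nb)]
  y1 <- sum(z == 1L) - c(0, cumsum(cnt1))[seq_len(nb)]
  d <- tabulate(k[ev], nbins = nb)
  s1 <- tabulate(k[ev & z == 1L], nbins = nb)
  keep <- d > 0
  list(d = d[keep], s1 = s1[keep], y1 = y1[keep], y0 = (y - y1)[keep])
}

breslow_loglik <- function(beta, tb) {
  # vectorised over beta for grid-search oracles
  vapply(beta, function(b) {
    sum(b * tb$s1 - tb$d * log(tb$y0 + tb$y1 * exp(b)))
  }, numeric(1))
}

cscox_engine <- function(time, status, z, cause) {
  tb <- breslow_tables(time, status, z, cause)
  n_events <- sum(tb$d)
  base <- list(cause = cause, n_events = n_events)
  # The maximiser is finite iff the score still changes sign at +/-infinity:
  # as beta -> +Inf the at-risk weight concentrates on arm 1 wherever it is
  # represented, and symmetrically for arm 0. Complete separation (all
  # target-cause events in one arm) is a special case.
  score_pos <- sum(tb$s1 - tb$d * (tb$y1 > 0))
  score_neg <- sum(tb$s1 - tb$d * (tb$y0 == 0))
  if (score_pos >= 0 || score_neg <= 0) {
    return(c(base, list(coefficient = NA_real_, standard_error = NA_real_,
                        wald_ci = c(NA_real_, NA_real_), p_value = NA_real_,
                        loglik = NA_real_, converged = FALSE, iterations = 0L)))
  }
  beta <- 0
  ll <- breslow_loglik(beta, tb)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    eb <- exp(beta)
    frac <- tb$y1 * eb / (tb$y0 + tb$y1 * eb)
    score <- sum(tb$s1 - tb$d * frac)
    info <- sum(tb$d * frac * (1 - frac))
    if (abs(score) < 1e-8) { converged <- TRUE; break }
    step <- score / info
    # step-halving if the likelihood would decrease
    repeat {
      ll_new <- breslow_loglik(beta + step, tb)
      if (ll_new >= ll - 1e-12 || abs(step) < 1e-10) break
      step <- step / 2
    }
    if (abs(step) < 1e-10) { converged <- TRUE; break }
    beta <- beta + step
    ll <- breslow_loglik(beta, tb)
  }
  eb <- exp(beta)
  frac <- tb$y1 * eb / (tb$y0 + tb$y1 * eb)
  info <- sum(tb$d * frac * (1 - frac))
  se <- 1 / sqrt(info)
  c(base, list(coefficient = beta, standard_error = se,
               wald_ci = beta + c(-1.96, 1.96) * se,
               p_value = 2 * stats::pnorm(-abs(beta / se)),
               loglik = ll, converged = converged, iterations = iter))
}

#' @export
print.cscox <- function(x, ...) {
  cat(sprintf("Cause-specific Cox model (cause %d, Breslow ties)\n", x$cause))
  if (!isTRUE(x$converged) && is.na(x$coefficient)) {
    cat("  did not converge (complete separation)\n")
    return(invisible(x))
  }
  cat(sprintf("  log CSH ratio %.4f (se %.4f), CSH ratio %.4f [%.4f, %.4f], p = %.4g\n",
              x$coefficient, x$standard_error, exp(x$coefficient),
              exp(x$wald_ci[1]), exp(x$wald_ci[2]), x$p_value))
  cat(sprintf("  %d events, n = %d, %d iterations\n", x$n_events, x$n, x$iterations))
  invisible(x)
}

#' @export
coef.cscox <- function(object, ...) c(group = object$coefficient)

#' @export
vcov.cscox <- function(object, ...) {
  matrix(object$standard_error^2, 1, 1, dimnames = list("group", "group"))
}

#' @export
confint.cscox <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  matrix(object$coefficient + c(-q, q) * object$standard_error, 1, 2,
         dimnames = list("group", sprintf("%g %%", c((1 - level) / 2,
                                                     1 - (1 - level) / 2) * 100)))
}
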