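# Nonparametric estimators for the two-cause competing-risks model.
#
# All estimators are right-continuous step functions built from the same
# per-time event/risk-set table. Tie convention: at a time carrying both
# events and censorings, events are processed first, i.e. subjects censored
# at t are still at risk for events at t (risk set = #\{observed time >= t\}).

# Per-time counts: unique observed times with cause-1 events d1, cause-2
# events d2, censorings d0 and the at-risk count Y (events-first ties).
risk_table <- function(data) {
  stopifnot(inherits(data, "crdata"))
  n <- nrow(data)
  ut <- sort(unique(data$time))
  k <- match(data$time, ut)
  cnt <- tabulate(k, nbins = length(ut))
  tab <- function(st) tabulate(k[data$status == st], nbins = length(ut))
  list(time = ut,
       d1 = tab(1L), d2 = tab(2L), d0 = tab(0L),
       Y = n - c(0, cumsum(cnt))[seq_along(ut)],
       n = n)
}

#' Nelson-Aalen estimator of a cumulative cause-specific hazard
#'
#' Estimates the cumulative cause-specific hazard \eqn{A_{0j}(t)} by summing
#' \eqn{d_j(s)/Y(s)} over observed cause-\eqn{j} event times \eqn{s \le t},
#' where \eqn{d_j(s)} is the number of cause-\eqn{j} events at \eqn{s} and
#' \eqn{Y(s)} the number at risk. The variance estimate accumulates
#' \eqn{d_j(s)/Y(s)^2}; pointwise 95% confidence limits use the
#' log transformation \eqn{\hat A \exp(\pm 1.96\, \widehat{se}/\hat A)}.
#'
#' @param data A [crdata] object.
#' @param cause Which cause-specific hazard, 1 (event of interest) or 2
#'   (competing event).
#' @return An object of class `"cumhaz"` (and `"crstep"`): a list with
#'   `time` (jump times), `inc` (increments), `est` (cumulative value at each
#'   jump), `var`, `se`, `lower`, `upper`, `cause` and `n`. Evaluate it at
#'   arbitrary times with [evaluate()]; beyond the last jump the value is
#'   frozen at the last estimate.
#' @examples
#' d <- crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))
#' na1 <- nelson_aalen(d, cause = 1)
#' evaluate(na1, 4)  # 1/4 + 1/1 = 1.25
#' @export
nelson_aalen <- function(data, cause = 1) {
  cause <- match_cause(cause)
  rt <- risk_table(data)
  d <- if (cause == 1L) rt$d1 else rt$d2
  keep <- d > 0
  inc <- d[keep] / rt$Y[keep]
  v <- cumsum(d[keep] / rt$Y[keep]^2)
  est <- cumsum(inc)
  se <- sqrt(v)
  structure(list(time = rt$time[keep], inc = inc, est = est,
                 var = v, se = se,
                 lower = ifelse(est > 0, est * exp(-1.96 * se / est), 0),
                 upper = ifelse(est > 0, est * exp(1.96 * se / est), 0),
                 cause = cause, n = rt$n),
            class = c("cumhaz", "crstep"))
}

match_cause <- function(cause) {
  if (!(length(cause) == 1L && cause %in% c(1, 2))) {
    stop_crsim("`cause` must be 1 or 2", "validation")
  }
  as.integer(cause)
}

#' Kaplan-Meier estimator of event or censoring survival
#'
#' With `role = "event"` estimates \eqn{P(T > t)} by the product-limit
#' formula over pooled cause-1 and cause-2 event times; this equals the
#' product-integral of the pooled Nelson-Aalen increments,
#' \eqn{\hat S(t) = \prod_{s \le t} (1 - \Delta\hat A_{01}(s) -
#' \Delta\hat A_{02}(s))}, exactly. With `role = "censoring"` the roles of
#' event (status 0) and censoring (status 1 or 2) are swapped, estimating the
#' censoring survival function used to draw censoring times in simulations.
#'
#' @param data A [crdata] object.
#' @param role `"event"` or `"censoring"`.
#' @return An object of class `"survcurve"` (and `"crstep"`): jump times
#'   `time`, values `est` (the survival value at each jump), `role`, `n`.
#'   [evaluate()] returns 1 before the first jump and freezes after the last.
#' @examples
#' d <- crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))
#' evaluate(kaplan_meier(d), c(1, 2, 4))       # 0.75 0.50 0.00
#' evaluate(kaplan_meier(d, "censoring"), 3)   # 0.5
#' @export
kaplan_meier <- function(data, role = c("event", "censoring")) {
  role <- match.arg(role)
  rt <- risk_table(data)
  d <- if (role == "event") rt$d1 + rt$d2 else rt$d0
  keep <- d > 0
  structure(list(time = rt$time[keep],
                 est = cumprod(1 - d[keep] / rt$Y[keep]),
                 role = role, n = rt$n),
            class = c("survcurve", "crstep"))
}

#' Aalen-Johansen estimator of a cumulative incidence function
#'
#' Plug-in estimator of \eqn{P(T \le t, X_T = j)}: the sum over observed
#' cause-\eqn{j} event times \eqn{s \le t} of \eqn{\hat S(s-)\,
#' \Delta\hat A_{0j}(s)}, with \eqn{\hat S(s-)} the left-limit Kaplan-Meier
#' value (1 before the first event time). The two estimated cumulative
#' incidence functions add up to \eqn{1 - \hat S(t)} exactly at every time.
#'
#' @inheritParams nelson_aalen
#' @return An object of class `"cif"` (and `"crstep"`): jump times, `inc`,
#'   `est` (cumulative incidence at each jump), `cause`, `n`. [evaluate()]
#'   returns 0 before the first jump.
#' @examples
#' d <- crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))
#' evaluate(aalen_johansen(d, 1), 4)  # 0.25 + 0.5 = 0.75
#' @export
aalen_johansen <- function(data, cause = 1) {
  cause <- match_cause(cause)
  rt <- risk_table(data)
  dj <- if (cause == 1L) rt$d1 else rt$d2
  dall <- rt$d1 + rt$d2
  ev <- dall > 0
  s <- cumprod(1 - dall[ev] / rt$Y[ev])
  s_left <- c(1, s[-length(s)])
  keep <- dj[ev] > 0
  inc <- (s_left * dj[ev] / rt$Y[ev])[keep]
  structure(list(time = rt$time[ev][keep], inc = inc, est = cumsum(inc),
                 cause = cause, n = rt$n),
            class = c("cif", "crstep"))
}

#' Evaluate a step-function estimate at given times
#'
#' All estimators in this package are right-continuous step functions.
#' `evaluate()` returns the estimate at arbitrary times: the baseline value
#' (0 for cumulative hazards and incidences, 1 for survival curves) before
#' the first jump, and the last value frozen beyond the last jump (curves are
#' never extrapolated).
#'
#' @param x A `"cumhaz"`, `"survcurve"`, `"cif"` object, or any object with
#'   `time`/`est` step data.
#' @param times Numeric vector of evaluation times.
#' @param ... Unused.
#' @return Numeric vector of the same length as `times`.
#' @export
evaluate <- function(x, times, ...) UseMethod("evaluate")

#' @export
evaluate.crstep <- function(x, times, ...) {
  base <- if (inherits(x, "survcurve")) 1 else 0
  c(base, x$est)[findInterval(times, x$time) + 1L]
}

step_df <- function(x) {
  out <- data.frame(time = x$time, estimate = x$est)
  if (!is.null(x$var)) {
    out$variance <- x$var
    out$lower <- x$lower
    out$upper <- x$upper
  }
  out
}

#' @export
as.data.frame.crstep <- function(x, ...) step_df(x)

#' Export an estimator as tidy CSV
#'
#' Writes columns `time, estimate` plus `variance, lower, upper` where
#' available, one row per jump.
#'
#' @param x A `"cumhaz"`, `"survcurve"` or `"cif"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimate_csv <- function(x, path) {
  utils::write.csv(step_df(x), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cumhaz <- function(x, ...) {
  cat(sprintf("Nelson-Aalen cumulative cause-%d hazard: %d jumps, A(max) = %.4f (n = %d)\n",
              x$cause, length(x$time), last_or(x$est, 0), x$n))
  invisible(x)
}

#' @export
print.survcurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier %s survival: %d jumps, S(max) = %.4f (n = %d)\n",
              x$role, length(x$time), last_or(x$est, 1), x$n))
  invisible(x)
}

#' @export
print.cif <- function(x, ...) {
  cat(sprintf("Aalen-Johansen cause-%d cumulative incidence: %d jumps, CIF(max) = %.4f (n = %d)\n",
              x$cause, length(x$time), last_or(x$est, 0), x$n))
  invisible(x)
}

last_or <- function(x, default) if (length(x)) x[length(x)] else default

#' Plot a step-function estimate
#'
#' Draws the estimate as a right-continuous step function; for cumulative
#' hazards the log-transformed pointwise 95% confidence limits are added as
#' dashed steps.
#'
#' @param x A `"cumhaz"`, `"survcurve"` or `"cif"` object.
#' @param conf Logical; draw confidence limits when available.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.crstep <- function(x, conf = TRUE, ...) {
  base <- if (inherits(x, "survcurve")) 1 else 0
  tt <- c(0, x$time)
  yy <- c(base, x$est)
  ylab <- if (inherits(x, "cumhaz")) "cumulative hazard"
          else if (inherits(x, "cif")) "cumulative incidence" else "survival"
  graphics::plot(tt, yy, type = "s", xlab = "time", ylab = ylab, ...)
  if (conf && !is.null(x$lower)) {
    graphics::lines(c(0, x$time), c(base, x$lower), type = "s", lty = 2)
    graphics::lines(c(0, x$time), c(base, x$upper), type = "s", lty = 2)
  }
  invisible(x)
}
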