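# The two-step simulation algorithm: draw the event time from the all-cause
# distribution, then the event type from a binomial experiment with the
# cause-1 probability attached to that time; finally impose independent
# right-censoring drawn from the law's censoring distribution.

#' Draw latent event times and types from a law
#'
#' Step 1 draws the event time from the discrete distribution given by
#' `(support, time_mass, tail_mass)`; a draw landing in the tail mass (the
#' probability the Kaplan-Meier estimator never spent) is returned as `Inf`
#' with cause `NA` -- such realisations are always censored once a censoring
#' time is attached. Step 2 draws the event type: cause 1 with the
#' probability attached to the drawn support point. Uses the current RNG
#' state.
#'
#' @param law An `"empirical_law"` object.
#' @param n Number of draws.
#' @return A list with numeric `time` (may contain `Inf`) and integer
#'   `cause` (1, 2, or `NA` for tail draws).
#' @export
draw_events <- function(law, n) {
  stopifnot(inherits(law, "empirical_law"), n >= 1)
  k <- length(law$support)
  idx <- sample.int(k + 1L, n, replace = TRUE,
                    prob = c(law$time_mass, law$tail_mass))
  tail <- idx > k
  time <- c(law$support, Inf)[idx]
  cause <- rep(NA_integer_, n)
  if (any(!tail)) {
    p1 <- law$type1_prob[idx[!tail]]
    cause[!tail] <- ifelse(stats::runif(sum(!tail)) < p1, 1L, 2L)
  }
  list(time = time, cause = cause)
}

draw_censoring <- function(law, n) {
  if (length(law$cens_support) == 0L) {
    stop_crsim("law has no censoring distribution", "law")
  }
  law$cens_support[sample.int(length(law$cens_support), n, replace = TRUE,
                              prob = law$cens_mass)]
}

#' Simulate a one-arm dataset from an empirical law
#'
#' Each subject receives a latent event time and type via [draw_events()]
#' and an independent censoring time from the law's censoring distribution.
#' The observed time is the minimum of the two; a tie (event time equal to
#' censoring time) counts as an observed event, mirroring the estimator-side
#' convention that events are processed before censorings, so that
#' estimate-simulate-estimate round trips are self-consistent. Tail draws
#' (event time beyond the largest observed time) lose to any finite
#' censoring time and are recorded as censored.
#'
#' @param object An `"empirical_law"` object.
#' @param nsim Number of subjects to simulate.
#' @param seed Optional integer seed; when given the output is fully
#'   reproducible.
#' @param group Optional group code (0/1) attached to all subjects.
#' @param ... Unused.
#' @return A [crdata] object with `nsim` rows.
#' @examples
#' d <- crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))
#' sim <- simulate(empirical_law(d), nsim = 100, seed = 1)
#' summary(sim)
#' @export
simulate.empirical_law <- function(object, nsim = 1, seed = NULL,
                                   group = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ev <- draw_events(object, nsim)
  cens <- draw_censoring(object, nsim)
  observed <- pmin(ev$time, cens)
  status <- ifelse(is.finite(ev$time) & ev$time <= cens, ev$cause, 0L)
  crdata(time = observed, status = status,
         group = if (!is.null(group)) rep(as.integer(group), nsim))
}

#' Simulate a two-arm trial under a scenario
#'
#' Builds the control and treatment laws implied by a [scenario] via
#' [apply_scenario()] (transformed baselines, proportional cause-specific
#' treatment effects, shared control censoring distribution) and simulates
#' the two arms.
#'
#' @inheritParams apply_scenario
#' @param seed Optional integer seed.
#' @return A [crdata] object with a `group` column (0 control, 1 treatment);
#'   control rows first.
#' @export
simulate_trial <- function(control, scen, seed = NULL) {
  laws <- apply_scenario(control, scen)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- simulate.empirical_law(laws$control, nsim = scen$n_control, group = 0L)
  trt <- simulate.empirical_law(laws$treatment, nsim = scen$n_treatment, group = 1L)
  out <- rbind(as.data.frame(ctrl), as.data.frame(trt))
  crdata(time = out$time, status = out$status, group = out$group)
}

# Replicate-seed spawning rule: a throwaway RNG seeded with the master seed
# draws one sub-seed per stream, so stream i depends only on (master, i) and
# streams are individually reproducible. The ambient RNG state is restored.
spawn_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}
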