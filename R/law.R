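# The discrete simulable law: event-time point masses from Kaplan-Meier
# drops, per-time event-type probabilities from Nelson-Aalen increments, a
# tail point mass for probability the Kaplan-Meier curve never spends, and a
# discrete censoring distribution.

#' Build the empirical law of a competing-risks dataset
#'
#' Turns a dataset into a discrete simulable law. Event times receive the
#' point masses of the distribution defined by the all-cause Kaplan-Meier
#' estimator (the drop at each event time); probability the curve never
#' spends because of right-censoring is assigned to a point mass beyond the
#' largest observed time (draws from it are always censored). At each event
#' time the probability that the event is of cause 1 is the ratio of
#' Nelson-Aalen increments, \eqn{d_1(s)/(d_1(s)+d_2(s))}. Censoring times
#' are described by the discrete distribution of the censoring-role
#' Kaplan-Meier estimator.
#'
#' If the censoring curve does not spend all of its mass (i.e. the largest
#' observed time is an event), the unspent censoring mass is assigned to a
#' point just after the largest observed time, with a warning.
#'
#' @param data A [crdata] object containing at least one event.
#' @return An object of class `"empirical_law"`: a list with `support`
#'   (event times), `time_mass`, `tail_mass`, `type1_prob`, and the
#'   censoring distribution `cens_support`, `cens_mass`.
#' @examples
#' d <- crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))
#' law <- empirical_law(d)
#' law$time_mass   # 0.25 0.25 0.50
#' law$tail_mass   # 0
#' @export
empirical_law <- function(data) {
  rt <- risk_table(data)
  dall <- rt$d1 + rt$d2
  ev <- dall > 0
  if (!any(ev)) stop_crsim("no events in dataset: empirical law undefined", "law")
  s <- cumprod(1 - dall[ev] / rt$Y[ev])
  s_left <- c(1, s[-length(s)])
  cens <- censoring_dist(rt)
  new_empirical_law(support = rt$time[ev],
                    time_mass = s_left - s,
                    tail_mass = s[length(s)],
                    type1_prob = rt$d1[ev] / dall[ev],
                    cens_support = cens$support,
                    cens_mass = cens$mass)
}

# Discrete censoring distribution from the censoring-role Kaplan-Meier; any
# unspent mass goes to a point just beyond the largest observed time.
censoring_dist <- function(rt) {
  cz <- rt$d0 > 0
  if (!any(cz)) {
    g <- numeric(0)
    support <- numeric(0)
    mass <- numeric(0)
    unspent <- 1
  } else {
    g <- cumprod(1 - rt$d0[cz] / rt$Y[cz])
    support <- rt$time[cz]
    mass <- c(1, g[-length(g)]) - g
    unspent <- g[length(g)]
  }
  if (unspent > 1e-12) {
    warning(warningCondition(
      sprintf("censoring distribution has %.4f unspent mass; assigning it beyond the largest observed time",
              unspent),
      class = c("crsim_censoring_warning", "warning", "condition")))
    tmax <- rt$time[length(rt$time)]
    support <- c(support, tmax + 1e-9 * max(1, tmax))
    mass <- c(mass, unspent)
  }
  list(support = support, mass = mass)
}

new_empirical_law <- function(support, time_mass, tail_mass, type1_prob,
                              cens_support, cens_mass) {
  structure(list(support = support, time_mass = time_mass,
                 tail_mass = tail_mass, type1_prob = type1_prob,
                 cens_support = cens_support, cens_mass = cens_mass),
            class = "empirical_law")
}

#' Rebuild a law from a pair of cumulative cause-specific hazards
#'
#' Reconstructs the discrete law implied by step cumulative hazards through
#' the discrete product-integral: \eqn{S(t) = \prod_{s \le t} (1 -
#' \Delta A_1(s) - \Delta A_2(s))}, event-time mass \eqn{S(s-)(\Delta A_1(s)
#' + \Delta A_2(s))}, tail mass \eqn{S} at the last jump and cause-1
#' probability \eqn{\Delta A_1(s)/(\Delta A_1(s)+\Delta A_2(s))}. Applied to
#' a dataset's own Nelson-Aalen estimators this inverts [empirical_law()]
#' exactly.
#'
#' A pooled increment above 1 means the hazard pair is not a distribution
#' (e.g. an inadmissible transformation or treatment effect); increments
#' within `1e-9` above 1 are clamped to 1, anything larger is an error
#' naming the offending time.
#'
#' @param cum_haz1,cum_haz2 `"cumhaz"` objects (or lists with `time` and
#'   `inc`) for causes 1 and 2.
#' @param censoring The censoring distribution: a censoring-role
#'   `"survcurve"`, an `"empirical_law"` (its censoring part is reused), or
#'   a list with `support` and `mass`.
#' @return An `"empirical_law"` object.
#' @export
law_from_hazards <- function(cum_haz1, cum_haz2, censoring) {
  support <- sort(unique(c(cum_haz1$time, cum_haz2$time)))
  a1 <- increments_on(cum_haz1, support)
  a2 <- increments_on(cum_haz2, support)
  if (any(a1 < 0) || any(a2 < 0)) {
    stop_crsim("negative hazard increment", "law")
  }
  pooled <- a1 + a2
  keep <- pooled > 0
  support <- support[keep]; a1 <- a1[keep]; a2 <- a2[keep]
  pooled <- pooled[keep]
  over <- pooled > 1
  if (any(pooled > 1 + 1e-9)) {
    stop_crsim(sprintf("pooled hazard increment %.6f > 1 at time %g: hazards do not define a distribution",
                       max(pooled), support[which.max(pooled)]), "law")
  }
  pooled[over] <- 1
  s <- cumprod(1 - pooled)
  s_left <- c(1, s[-length(s)])
  cens <- as_cens_dist(censoring)
  new_empirical_law(support = support,
                    time_mass = s_left * pooled,
                    tail_mass = if (length(s)) s[length(s)] else 1,
                    type1_prob = a1 / pooled,
                    cens_support = cens$support, cens_mass = cens$mass)
}

increments_on <- function(h, support) {
  inc <- numeric(length(support))
  if (length(h$time)) inc[match(h$time, support)] <- h$inc
  inc
}

as_cens_dist <- function(censoring) {
  if (inherits(censoring, "empirical_law")) {
    return(list(support = censoring$cens_support, mass = censoring$cens_mass))
  }
  if (inherits(censoring, "survcurve")) {
    if (censoring$role != "censoring") {
      stop_crsim("`censoring` must be a censoring-role survival curve", "validation")
    }
    g <- censoring$est
    mass <- c(1, g[-length(g)]) - g
    support <- censoring$time
    unspent <- if (length(g)) g[length(g)] else 1
    if (unspent > 1e-12) {
      warning(warningCondition(
        sprintf("censoring distribution has %.4f unspent mass; assigning it beyond the largest jump time",
                unspent),
        class = c("crsim_censoring_warning", "warning", "condition")))
      tmax <- if (length(support)) support[length(support)] else 1
      support <- c(support, tmax + 1e-9 * max(1, tmax))
      mass <- c(mass, unspent)
    }
    return(list(support = support, mass = mass))
  }
  stopifnot(is.list(censoring), !is.null(censoring$support), !is.null(censoring$mass))
  censoring[c("support", "mass")]
}

#' Cumulative incidence functions implied by a law
#'
#' The discrete analogue of the plug-in cumulative incidence: cumulative sum
#' of `time_mass * P(cause = j | T = s)` over the support.
#'
#' @param law An `"empirical_law"` object.
#' @param cause 1 or 2.
#' @return A `"cif"` step object.
#' @export
implied_cif <- function(law, cause = 1) {
  cause <- match_cause(cause)
  p <- if (cause == 1L) law$type1_prob else 1 - law$type1_prob
  inc <- law$time_mass * p
  structure(list(time = law$support, inc = inc, est = cumsum(inc),
                 cause = cause, n = NA_integer_),
            class = c("cif", "crstep"))
}

#' @export
print.empirical_law <- function(x, ...) {
  cat(sprintf("Empirical competing-risks law: %d support points, tail mass %.4f\n",
              length(x$support), x$tail_mass))
  cat(sprintf("  event mass %.4f, censoring distribution on %d points\n",
              sum(x$time_mass), length(x$cens_support)))
  invisible(x)
}

# ---- scenarios ------------------------------------------------------------

built_in_transforms <- list(
  identity = function(x) x,
  root4    = function(x) x^(1 / 4),
  square   = function(x) x^2
)

resolve_transform <- function(tr, what) {
  if (is.function(tr)) {
    if (abs(tr(0)) > 1e-12) stop_crsim(sprintf("%s must map 0 to 0", what), "validation")
    grid <- seq(0, 10, length.out = 201)
    if (any(diff(tr(grid)) < -1e-12)) {
      stop_crsim(sprintf("%s must be nondecreasing", what), "validation")
    }
    return(list(name = "custom", fn = tr))
  }
  tr <- as.character(tr)
  if (tr %in% c("none", "id")) tr <- "identity"
  if (!tr %in% names(built_in_transforms)) {
    stop_crsim(sprintf("unknown transformation '%s' for %s (use identity, root4, square, or a function)",
                       tr, what), "validation")
  }
  list(name = tr, fn = built_in_transforms[[tr]])
}

#' Define a two-arm simulation scenario
#'
#' A scenario specifies log cause-specific hazard ratios `beta1` and `beta2`
#' for the treatment arm (so the treatment hazards are
#' \eqn{e^{\beta_j}\alpha_{0j}(t)}), optional monotone transformations of the
#' control cumulative baseline hazards (applied to both arms before the
#' hazard ratios act), and the arm sizes.
#'
#' @param beta1,beta2 Log cause-specific hazard ratios for the event of
#'   interest and the competing event.
#' @param transform1,transform2 Transformation of the cumulative baseline
#'   hazard for each cause: `"identity"` (or `"none"`), `"root4"`
#'   (\eqn{x \mapsto x^{1/4}}, amplifies a cumulative hazard below 1),
#'   `"square"` (\eqn{x \mapsto x^2}, shrinks it), or a user function with
#'   \eqn{f(0)=0}, nondecreasing.
#' @param n_control,n_treatment Subjects per arm.
#' @return An object of class `"scenario"`.
#' @examples
#' scenario(beta1 = -0.3, beta2 = 0)
#' @export
scenario <- function(beta1, beta2, transform1 = "identity",
                     transform2 = "identity", n_control = 500,
                     n_treatment = 500) {
  stopifnot(is.numeric(beta1), is.numeric(beta2),
            n_control >= 1, n_treatment >= 1)
  structure(list(beta1 = beta1, beta2 = beta2,
                 transform1 = resolve_transform(transform1, "transform1"),
                 transform2 = resolve_transform(transform2, "transform2"),
                 n_control = as.integer(n_control),
                 n_treatment = as.integer(n_treatment)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario: beta1 = %g (HR %.3f), beta2 = %g (HR %.3f)\n",
              x$beta1, exp(x$beta1), x$beta2, exp(x$beta2)))
  cat(sprintf("  baseline transforms: %s / %s; n = %d + %d per trial\n",
              x$transform1$name, x$transform2$name, x$n_control, x$n_treatment))
  invisible(x)
}

transform_hazard <- function(h, fn) {
  cum <- fn(cumsum(h$inc))
  list(time = h$time, inc = diff(c(0, cum)))
}

scale_hazard <- function(h, factor) list(time = h$time, inc = h$inc * factor)

#' Apply a scenario to control-group hazards
#'
#' Builds the pair of laws a scenario implies. The control law uses the
#' transformed cumulative baseline hazards (transform applied to the
#' cumulative value, increments recovered by differencing on the original
#' support); the treatment law scales those increments by
#' \eqn{e^{\beta_j}}. Both arms share the control censoring distribution.
#'
#' @param control A [crdata] object for the control group, or a list with
#'   elements `h1`, `h2` (`"cumhaz"` objects) and `censoring` (accepted by
#'   [law_from_hazards()]).
#' @param scen A [scenario] object.
#' @return A list with `"empirical_law"` elements `control` and `treatment`.
#' @export
apply_scenario <- function(control, scen) {
  stopifnot(inherits(scen, "scenario"))
  cc <- control_components(control)
  b1 <- transform_hazard(cc$h1, scen$transform1$fn)
  b2 <- transform_hazard(cc$h2, scen$transform2$fn)
  list(control = law_from_hazards(b1, b2, cc$censoring),
       treatment = law_from_hazards(scale_hazard(b1, exp(scen$beta1)),
                                    scale_hazard(b2, exp(scen$beta2)),
                                    cc$censoring))
}

control_components <- function(control) {
  if (inherits(control, "crdata")) {
    list(h1 = nelson_aalen(control, 1), h2 = nelson_aalen(control, 2),
         censoring = kaplan_meier(control, "censoring"))
  } else {
    stopifnot(is.list(control), !is.null(control$h1), !is.null(control$h2),
              !is.null(control$censoring))
    control
  }
}

# ---- JSON serialisation ---------------------------------------------------

#' Serialize an empirical law to JSON
#'
#' @param law An `"empirical_law"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_law_json <- function(law, path) {
  stopifnot(inherits(law, "empirical_law"))
  jsonlite::write_json(unclass(law), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an empirical law from JSON
#'
#' @param path Path written by [write_law_json()].
#' @return An `"empirical_law"` object.
#' @export
read_law_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  law <- new_empirical_law(support = as.numeric(x$support),
                           time_mass = as.numeric(x$time_mass),
                           tail_mass = as.numeric(x$tail_mass),
                           type1_prob = as.numeric(x$type1_prob),
                           cens_support = as.numeric(x$cens_support),
                           cens_mass = as.numeric(x$cens_mass))
  validate_law(law)
}

validate_law <- function(law) {
  tot <- sum(law$time_mass) + law$tail_mass
  if (abs(tot - 1) > 1e-8) {
    stop_crsim(sprintf("law masses sum to %.10f, not 1", tot), "law")
  }
  if (any(law$type1_prob < -1e-12 | law$type1_prob > 1 + 1e-12)) {
    stop_crsim("type1_prob outside [0, 1]", "law")
  }
  law
}

#' Read a scenario (or list of scenarios) from JSON
#'
#' The schema is an object (or array of objects) with fields `beta1`,
#' `beta2`, optional `transform1`, `transform2` (names of built-in
#' transformations), `n_control`, `n_treatment`.
#'
#' @param path Path to a JSON file.
#' @return A list of [scenario] objects.
#' @export
read_scenarios_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$beta1)) x <- list(x)
  lapply(x, function(s) {
    for (fld in c("beta1", "beta2")) {
      if (is.null(s[[fld]]) || !is.numeric(s[[fld]])) {
        stop_crsim(sprintf("scenario JSON: missing or non-numeric field '%s'", fld),
                   "validation")
      }
    }
    scenario(beta1 = s$beta1, beta2 = s$beta2,
             transform1 = s$transform1 %||% "identity",
             transform2 = s$transform2 %||% "identity",
             n_control = s$n_control %||% 500,
             n_treatment = s$n_treatment %||% 500)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
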