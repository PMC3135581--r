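# Replicated scenario studies: simulate two-arm trials from a control
# dataset's empirical law under a scenario, fit both cause-specific Cox
# models per replicate, and aggregate bias, empirical confidence intervals,
# Wald coverage and empirical power. Also the point-mass diagnostic that
# compares the two arms' discrete event-time distributions.

#' Run one simulation scenario
#'
#' Per replicate: simulate a two-arm trial from the control group's
#' (transformed) empirical law under the scenario, fit cause-specific Cox
#' models for both causes, and record coefficient, standard error and Wald
#' test. Aggregates across replicates, per cause: the mean estimate, the
#' empirical 95% confidence interval (2.5th and 97.5th percentiles of the
#' replicate estimates, interpolated quantiles), the coverage of the 95%
#' Wald interval for the true coefficient, and the empirical power
#' (percentage of replicates with two-sided Wald p < 0.05).
#'
#' Replicates use independent sub-seeds spawned from `seed`, so each
#' replicate is individually reproducible and results do not depend on how
#' many other scenarios run in the same session. Replicates whose fit does
#' not converge (e.g. complete separation) are counted in `n_failed` and
#' excluded from the aggregates.
#'
#' @inheritParams apply_scenario
#' @param n_replicates Number of simulation replicates.
#' @param seed Integer master seed.
#' @return An object of class `"scenario_result"`: a list with `per_cause`
#'   (a data frame with rows for causes 1 and 2 and columns `true_beta`,
#'   `mean_estimate`, `ci_lower`, `ci_upper`, `coverage`, `power` -- the two
#'   percentages on the 0-100 scale), `n_replicates`, `n_failed`, `scenario`
#'   and the replicate-level `estimates`/`std_errors` matrices.
#' @export
run_scenario <- function(control, scen, n_replicates = 1000, seed = 1) {
  stopifnot(inherits(scen, "scenario"), n_replicates >= 1)
  laws <- apply_scenario(control, scen)
  seeds <- spawn_seeds(seed, n_replicates)
  est <- se <- matrix(NA_real_, n_replicates, 2)
  for (r in seq_len(n_replicates)) {
    set.seed(seeds[r])
    ctrl <- simulate.empirical_law(laws$control, nsim = scen$n_control)
    trt <- simulate.empirical_law(laws$treatment, nsim = scen$n_treatment)
    time <- c(ctrl$time, trt$time)
    status <- c(ctrl$status, trt$status)
    z <- rep(c(0L, 1L), c(scen$n_control, scen$n_treatment))
    for (cause in 1:2) {
      fit <- tryCatch(cscox_engine(time, status, z, cause),
                      crsim_error = function(e) NULL)
      if (!is.null(fit) && isTRUE(fit$converged)) {
        est[r, cause] <- fit$coefficient
        se[r, cause] <- fit$standard_error
      }
    }
  }
  aggregate_replicates(est, se, c(scen$beta1, scen$beta2), scen, n_replicates)
}

# Aggregation of replicate-level fits into the scenario-result metrics; a
# replicate contributes only if both cause-specific fits converged.
aggregate_replicates <- function(est, se, true_beta, scen = NULL,
                                 n_replicates = nrow(est)) {
  ok <- stats::complete.cases(est) & stats::complete.cases(se)
  if (!any(ok)) stop_crsim("all replicates failed", "study")
  per_cause <- do.call(rbind, lapply(1:2, function(j) {
    b <- est[ok, j]
    s <- se[ok, j]
    ci <- stats::quantile(b, c(0.025, 0.975), names = FALSE, type = 7)
    covered <- abs(b - true_beta[j]) <= 1.96 * s
    reject <- abs(b) > 1.96 * s
    data.frame(cause = j, true_beta = true_beta[j], mean_estimate = mean(b),
               ci_lower = ci[1], ci_upper = ci[2],
               coverage = 100 * mean(covered), power = 100 * mean(reject))
  }))
  structure(list(per_cause = per_cause, n_replicates = n_replicates,
                 n_failed = sum(!ok), scenario = scen),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario study: %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  pc <- x$per_cause
  for (j in 1:2) {
    cat(sprintf("  cause %d: true %+0.2f, mean %+0.3f, emp. 95%% CI [%+.3f, %+.3f], coverage %.1f%%, power %.1f%%\n",
                pc$cause[j], pc$true_beta[j], pc$mean_estimate[j],
                pc$ci_lower[j], pc$ci_upper[j], pc$coverage[j], pc$power[j]))
  }
  invisible(x)
}

#' The built-in scenario table
#'
#' The ten scenarios of the package's reference study: log hazard ratios
#' `beta1` in \{-0.1, -0.3\} crossed with `beta2` in \{0, 0.3, -0.3\} and
#' monotone transformations of the cumulative baseline hazards
#' (`root4` amplifies a cumulative hazard below 1, `square` shrinks it).
#'
#' @param n_control,n_treatment Subjects per arm (defaults 500/500).
#' @return A named list of ten [scenario] objects.
#' @export
table1_scenarios <- function(n_control = 500, n_treatment = 500) {
  rows <- list(
    list(-0.1, 0,    "identity", "identity"),
    list(-0.1, 0,    "root4",    "identity"),
    list(-0.1, 0.3,  "identity", "identity"),
    list(-0.1, 0.3,  "identity", "square"),
    list(-0.1, -0.3, "square",   "root4"),
    list(-0.3, 0,    "identity", "identity"),
    list(-0.3, 0,    "root4",    "identity"),
    list(-0.3, 0.3,  "identity", "identity"),
    list(-0.3, 0.3,  "identity", "square"),
    list(-0.3, -0.3, "square",   "root4"))
  out <- lapply(rows, function(r) {
    scenario(beta1 = r[[1]], beta2 = r[[2]], transform1 = r[[3]],
             transform2 = r[[4]], n_control = n_control,
             n_treatment = n_treatment)
  })
  names(out) <- paste0("scenario_", seq_along(out))
  out
}

#' Run a list of scenarios and tabulate the results
#'
#' Maps [run_scenario()] over a scenario list with per-scenario sub-seeds
#' spawned from the master seed (so each row is reproducible in isolation)
#' and collects one row per scenario with both causes' metrics. A scenario
#' that errors is reported as an `NA` row and the run continues.
#'
#' @inheritParams run_scenario
#' @param scenarios A list of [scenario] objects, e.g. [table1_scenarios()].
#' @param file Optional path; when given the report is also written as CSV.
#' @return A data frame with one row per scenario: `scenario`, `beta1`,
#'   `mean1`, `ci1_lower`, `ci1_upper`, `coverage1`, `power1`, then the same
#'   for cause 2, plus `n_failed`.
#' @export
run_table <- function(control, scenarios = table1_scenarios(),
                      n_replicates = 1000, seed = 1, file = NULL) {
  if (length(scenarios) == 0L) {
    out <- empty_table_report()
  } else {
    seeds <- spawn_seeds(seed, length(scenarios))
    rows <- lapply(seq_along(scenarios), function(i) {
      res <- tryCatch(
        run_scenario(control, scenarios[[i]], n_replicates, seeds[i]),
        crsim_error = function(e) {
          warning(sprintf("scenario %d failed: %s", i, conditionMessage(e)))
          NULL
        })
      report_row(i, scenarios[[i]], res)
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

report_row <- function(i, scen, res) {
  row <- data.frame(scenario = i, beta1 = scen$beta1,
                    mean1 = NA_real_, ci1_lower = NA_real_, ci1_upper = NA_real_,
                    coverage1 = NA_real_, power1 = NA_real_,
                    beta2 = scen$beta2,
                    mean2 = NA_real_, ci2_lower = NA_real_, ci2_upper = NA_real_,
                    coverage2 = NA_real_, power2 = NA_real_,
                    n_failed = NA_integer_)
  if (!is.null(res)) {
    pc <- res$per_cause
    row[, c("mean1", "ci1_lower", "ci1_upper", "coverage1", "power1")] <-
      pc[1, c("mean_estimate", "ci_lower", "ci_upper", "coverage", "power")]
    row[, c("mean2", "ci2_lower", "ci2_upper", "coverage2", "power2")] <-
      pc[2, c("mean_estimate", "ci_lower", "ci_upper", "coverage", "power")]
    row$n_failed <- res$n_failed
  }
  row
}

empty_table_report <- function() {
  data.frame(scenario = integer(0), beta1 = numeric(0), mean1 = numeric(0),
             ci1_lower = numeric(0), ci1_upper = numeric(0),
             coverage1 = numeric(0), power1 = numeric(0), beta2 = numeric(0),
             mean2 = numeric(0), ci2_lower = numeric(0), ci2_upper = numeric(0),
             coverage2 = numeric(0), power2 = numeric(0),
             n_failed = integer(0))
}

#' Compare the point masses of two arms' event-time distributions
#'
#' The diagnostic behind the two-step reading of a scenario: per support
#' point, the event-time point mass in each arm (step 1 of the algorithm),
#' or -- with `restriction = "type1"` -- the mass carried by cause-1 events,
#' `time_mass * type1_prob` (step 2). Restricted to a time window to avoid
#' the steep ends of the observed range, and flagging, at each time, which
#' arm carries strictly more mass.
#'
#' @param control_law,treatment_law `"empirical_law"` objects (normally the
#'   pair returned by [apply_scenario()]).
#' @param window Numeric length-2 time window; support points outside it are
#'   dropped.
#' @param restriction `"all"` (all event times) or `"type1"` (only times
#'   carrying cause-1 mass).
#' @return An object of class `"point_mass_comparison"`: a data frame with
#'   columns `time`, `mass_control`, `mass_treatment`, `control_larger`,
#'   `treatment_larger`, with the window and restriction as attributes.
#' @export
point_mass_comparison <- function(control_law, treatment_law,
                                  window = c(0.07, 5.4),
                                  restriction = c("all", "type1")) {
  restriction <- match.arg(restriction)
  stopifnot(inherits(control_law, "empirical_law"),
            inherits(treatment_law, "empirical_law"),
            length(window) == 2L, window[1] < window[2])
  times <- sort(unique(c(control_law$support, treatment_law$support)))
  times <- times[times >= window[1] & times <= window[2]]
  if (length(times) == 0L) stop_crsim("no support points in window", "study")
  mass_at <- function(law, times) {
    m <- law$time_mass
    if (restriction == "type1") m <- m * law$type1_prob
    out <- numeric(length(times))
    hit <- match(times, law$support)
    out[!is.na(hit)] <- m[hit[!is.na(hit)]]
    out
  }
  mc <- mass_at(control_law, times)
  mt <- mass_at(treatment_law, times)
  if (restriction == "type1") {
    keep <- mc > 0 | mt > 0
    times <- times[keep]; mc <- mc[keep]; mt <- mt[keep]
  }
  out <- data.frame(time = times, mass_control = mc, mass_treatment = mt,
                    control_larger = mc > mt, treatment_larger = mt > mc)
  attr(out, "window") <- window
  attr(out, "restriction") <- restriction
  class(out) <- c("point_mass_comparison", "data.frame")
  out
}

#' Plot a point-mass comparison
#'
#' Mirrored bar display: control masses point down, treatment masses point
#' up; at each time the arm with the strictly larger mass is drawn black,
#' the other grey.
#'
#' @param x A `"point_mass_comparison"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.point_mass_comparison <- function(x, ...) {
  m <- max(x$mass_control, x$mass_treatment)
  graphics::plot(range(x$time), c(-m, m), type = "n", xlab = "time",
                 ylab = "point mass (control below, treatment above)", ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::segments(x$time, 0, x$time, -x$mass_control,
                     col = ifelse(x$control_larger, "black", "grey60"))
  graphics::segments(x$time, 0, x$time, x$mass_treatment,
                     col = ifelse(x$treatment_larger, "black", "grey60"))
  invisible(x)
}

#' Empirical power across candidate sample sizes
#'
#' Re-runs a scenario at each candidate per-arm sample size and reports the
#' empirical power per cause with its binomial Monte-Carlo standard error --
#' the simulation-based alternative to closed-form sample-size formulas:
#' any control dataset (or pilot data resembling the anticipated control
#' arm) defines the law, and power is read off the replicates.
#'
#' @inheritParams run_scenario
#' @param n_grid Integer vector of per-arm sample sizes (both arms get the
#'   same n).
#' @return A data frame with columns `n`, `power1`, `se1`, `power2`, `se2`,
#'   `n_failed` (powers in percent).
#' @export
power_curve <- function(control, scen, n_grid, n_replicates = 1000, seed = 1) {
  stopifnot(length(n_grid) >= 1)
  seeds <- spawn_seeds(seed, length(n_grid))
  rows <- lapply(seq_along(n_grid), function(i) {
    sc <- scenario(beta1 = scen$beta1, beta2 = scen$beta2,
                   transform1 = scen$transform1$fn, transform2 = scen$transform2$fn,
                   n_control = n_grid[i], n_treatment = n_grid[i])
    res <- run_scenario(control, sc, n_replicates, seeds[i])
    used <- res$n_replicates - res$n_failed
    p <- res$per_cause$power / 100
    data.frame(n = n_grid[i],
               power1 = 100 * p[1], se1 = 100 * sqrt(p[1] * (1 - p[1]) / used),
               power2 = 100 * p[2], se2 = 100 * sqrt(p[2] * (1 - p[2]) / used),
               n_failed = res$n_failed)
  })
  do.call(rbind, rows)
}
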