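# Shared fixtures and independent oracles for the test suite.

# The worked 4-subject dataset used throughout: risk sets 4, 3, 2, 1.
hand_data <- function() crdata(time = c(1, 2, 3, 4), status = c(1, 2, 0, 1))

# Random competing-risks dataset with ties (times on a coarse grid so
# discrete-law behaviour is exercised).
random_crdata <- function(n, seed, tie_grid = 40) {
  set.seed(seed)
  tt <- ceiling(stats::runif(n) * tie_grid) / tie_grid * 5
  status <- sample(0:2, n, replace = TRUE, prob = c(0.35, 0.4, 0.25))
  crdata(time = tt, status = status)
}

# Independent Breslow log partial likelihood computed directly from the
# subject-level data (no shared code with the package's fitter), vectorised
# over beta for grid searches.
oracle_breslow_loglik <- function(beta, time, status, z, cause) {
  ev_times <- sort(unique(time[status == cause]))
  ll <- numeric(length(beta))
  for (t in ev_times) {
    at_risk <- time >= t
    dz <- z[time == t & status == cause]
    n1 <- sum(z[at_risk] == 1)
    n0 <- sum(at_risk) - n1
    ll <- ll + beta * sum(dz) - length(dz) * log(n0 + n1 * exp(beta))
  }
  ll
}

# Dense grid maximiser of the Breslow partial likelihood on [-5, 5].
oracle_grid_beta <- function(data, cause, step = 1e-4) {
  grid <- seq(-5, 5, by = step)
  ll <- oracle_breslow_loglik(grid, data$time, data$status, data$group, cause)
  grid[which.max(ll)]
}

# A library of small (<= 10 subjects) two-arm datasets for the Cox oracle
# checks, including ties, censoring and both causes.
small_cox_fixtures <- function() {
  list(
    # spec'd 3-subject example: control events at 1 and 3, treated at 2
    crdata(time = c(1, 2, 3), status = c(1, 1, 1), group = c(0, 1, 0)),
    crdata(time = c(1, 1, 2, 3, 4), status = c(1, 2, 1, 0, 1),
           group = c(0, 1, 1, 0, 1)),
    crdata(time = c(1, 1, 1, 2, 2, 3, 3, 4, 5, 6),
           status = c(1, 1, 2, 0, 1, 2, 1, 0, 1, 0),
           group = c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1)),
    crdata(time = c(2, 2, 2, 2, 5, 5, 7, 8), status = c(1, 1, 1, 2, 1, 0, 1, 2),
           group = c(0, 0, 1, 1, 1, 0, 1, 0)))
}

# Memoised heavy computations shared across acceptance-test blocks. All
# seeds fixed; the study conditions are 1000 replicates of 500 per arm on a
# 636-subject calibrated control cohort.
.acc_cache <- new.env(parent = emptyenv())
acc_get <- function(key, fun) {
  if (is.null(.acc_cache[[key]])) .acc_cache[[key]] <- fun()
  .acc_cache[[key]]
}
acc_spec <- function() acc_get("spec", calibrate_fixture)
acc_control <- function() {
  acc_get("control", function() generate_fixture(acc_spec(), n = 636, seed = 4))
}
acc_scen1 <- function() {
  acc_get("scen1", function() {
    run_scenario(acc_control(), scenario(beta1 = -0.1, beta2 = 0),
                 n_replicates = 1000, seed = 1001)
  })
}
acc_scen6 <- function() {
  acc_get("scen6", function() {
    run_scenario(acc_control(), scenario(beta1 = -0.3, beta2 = 0),
                 n_replicates = 1000, seed = 1006)
  })
}
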