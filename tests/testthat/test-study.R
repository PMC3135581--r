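test_that("replicate aggregation is exact arithmetic", {
  # three synthetic fits, cause-1 column hand-computed
  est <- cbind(c(-0.5, -0.3, -0.1), c(0.1, 0.0, -0.1))
  se <- matrix(0.1, 3, 2)
  res <- crsim:::aggregate_replicates(est, se, true_beta = c(-0.3, 0))
  pc <- res$per_cause
  expect_equal(pc$mean_estimate[1], -0.3)
  # type-7 interpolated percentiles of (-0.5, -0.3, -0.1)
  expect_equal(pc$ci_lower[1], -0.49)
  expect_equal(pc$ci_upper[1], -0.11)
  # only the middle replicate's Wald CI covers -0.3 (0.196 half-width)
  expect_equal(pc$coverage[1], 100 / 3)
  # |est| > 0.196 rejects: replicates 1 and 2
  expect_equal(pc$power[1], 200 / 3)
  expect_equal(res$n_failed, 0)

  # the degenerate case: every replicate estimates -0.3 with se 0.2/1.96
  est <- matrix(-0.3, 5, 2)
  se <- matrix(0.2 / 1.96, 5, 2)
  res <- crsim:::aggregate_replicates(est, se, true_beta = c(-0.3, -0.3))
  expect_equal(res$per_cause$mean_estimate, c(-0.3, -0.3))
  expect_equal(res$per_cause$coverage, c(100, 100))
  expect_equal(res$per_cause$power, c(100, 100))
})

test_that("failed replicates are excluded and counted", {
  est <- cbind(c(-0.2, NA, -0.4), c(0, 0.1, NA))
  se <- matrix(0.1, 3, 2)
  res <- crsim:::aggregate_replicates(est, se, true_beta = c(-0.3, 0))
  expect_equal(res$n_failed, 2)
  expect_equal(res$per_cause$mean_estimate[1], -0.2)
  est[] <- NA_real_
  expect_error(crsim:::aggregate_replicates(est, se, c(0, 0)),
               class = "crsim_study_error")
})

test_that("the built-in scenario table has the ten published settings", {
  scens <- table1_scenarios()
  expect_length(scens, 10)
  betas <- t(vapply(scens, function(s) c(s$beta1, s$beta2), numeric(2)))
  expect_setequal(paste(betas[, 1], betas[, 2]),
                  c("-0.1 0", "-0.1 0.3", "-0.1 -0.3",
                    "-0.3 0", "-0.3 0.3", "-0.3 -0.3"))
  tr <- vapply(scens, function(s) s$transform1$name, character(1))
  expect_equal(unname(tr[c(2, 5, 7, 10)]),
               c("root4", "square", "root4", "square"))
  tr2 <- vapply(scens, function(s) s$transform2$name, character(1))
  expect_equal(unname(tr2[c(4, 5, 9, 10)]),
               c("square", "root4", "square", "root4"))
  expect_true(all(vapply(scens, function(s) s$n_control, integer(1)) == 500L))
})

test_that("scenario rows are seed-isolated and the study is deterministic", {
  control <- generate_fixture(calibrate_fixture(), n = 636, seed = 40)
  scens <- table1_scenarios(n_control = 200, n_treatment = 200)[c(1, 6)]
  one <- run_table(control, scens[1], n_replicates = 8, seed = 5)
  both <- run_table(control, scens, n_replicates = 8, seed = 5)
  expect_equal(both[1, ], one[1, ])
  again <- run_table(control, scens, n_replicates = 8, seed = 5)
  expect_identical(both, again)
  expect_equal(nrow(run_table(control, list(), n_replicates = 8, seed = 5)), 0)
})

test_that("point-mass comparison flags the arm with more mass", {
  law <- suppressWarnings(empirical_law(random_crdata(100, 61)))
  same <- point_mass_comparison(law, law, window = range(law$support))
  expect_false(any(same$control_larger) || any(same$treatment_larger))

  shifted <- law
  shifted$support <- law$support + 2          # all mass moved later
  pm <- point_mass_comparison(law, shifted,
                              window = c(0, max(shifted$support)))
  early <- pm$time < min(shifted$support)
  expect_true(all(pm$control_larger[early][pm$mass_control[early] > 0]))
  late <- pm$time > max(law$support)
  expect_true(all(pm$treatment_larger[late][pm$mass_treatment[late] > 0]))
  expect_error(point_mass_comparison(law, law, window = c(1000, 1001)),
               class = "crsim_study_error")
})

test_that("unidirectional effects migrate type-1 mass to later times", {
  # beta2 < beta1 < 0 with square/root4 transforms: the treated arm loses
  # early cause-1 mass but gains it late, so the larger-mass flag moves from
  # the control to the treatment arm over time
  control <- generate_fixture(calibrate_fixture(), n = 5000, seed = 62)
  laws <- apply_scenario(control, scenario(beta1 = -0.1, beta2 = -0.3,
                                           transform1 = "square",
                                           transform2 = "root4"))
  pm <- point_mass_comparison(laws$control, laws$treatment,
                              window = c(0.07, 5.4), restriction = "type1")
  third <- quantile(pm$time, c(1 / 3, 2 / 3))
  early_share <- mean(pm$treatment_larger[pm$time < third[1]])
  late_share <- mean(pm$treatment_larger[pm$time > third[2]])
  expect_gt(late_share, early_share)
  expect_gt(late_share, 0.9)
})

test_that("power grows with sample size and respects the null", {
  control <- generate_fixture(calibrate_fixture(), n = 636, seed = 41)
  pw <- power_curve(control, scenario(-0.5, 0), n_grid = c(60, 400),
                    n_replicates = 120, seed = 9)
  expect_equal(pw$n, c(60, 400))
  expect_gt(pw$power1[2], pw$power1[1])
  # cause 2 is null: empirical power estimates the 5% size
  null_pw <- power_curve(control, scenario(0, 0), n_grid = 300,
                         n_replicates = 250, seed = 10)
  expect_gt(null_pw$power1, 0.5)
  expect_lt(null_pw$power1, 12)
})
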