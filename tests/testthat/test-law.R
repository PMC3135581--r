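test_that("empirical law matches the hand example", {
  # the largest observed time is an event, so the censoring curve has 0.5
  # unspent mass which is parked just past the end, with a warning
  expect_warning(law <- empirical_law(hand_data()),
                 class = "crsim_censoring_warning")
  expect_equal(law$support, c(1, 2, 4))
  expect_equal(law$time_mass, c(0.25, 0.25, 0.5))
  expect_equal(law$tail_mass, 0)
  expect_equal(law$type1_prob, c(1, 0, 1))
  expect_equal(law$cens_support[1], 3)
  expect_gt(law$cens_support[2], 4)
  expect_equal(law$cens_mass, c(0.5, 0.5))
})

test_that("tied causes at one time give pooled-count type probabilities", {
  d <- crdata(time = c(2, 2, 2, 5), status = c(1, 1, 2, 0))
  law <- suppressWarnings(empirical_law(d))
  expect_equal(law$type1_prob, 2 / 3)
})

test_that("a dataset without events has no law", {
  expect_error(empirical_law(crdata(time = 1:3, status = c(0, 0, 0))),
               class = "crsim_law_error")
})

test_that("law masses always sum to one", {
  for (seed in 1:6) {
    d <- random_crdata(150, seed + 50)
    law <- suppressWarnings(empirical_law(d))
    expect_equal(sum(law$time_mass) + law$tail_mass, 1, tolerance = 1e-12)
    expect_true(all(law$type1_prob >= 0 & law$type1_prob <= 1))
    expect_equal(sum(law$cens_mass), 1, tolerance = 1e-12)
  }
})

test_that("law_from_hazards performs the discrete product-integral", {
  cens <- list(support = 10, mass = 1)
  l1 <- law_from_hazards(list(time = 1, inc = 0.5), list(time = 1, inc = 0.5),
                         cens)
  expect_equal(l1$time_mass, 1)
  expect_equal(l1$tail_mass, 0)
  expect_equal(l1$type1_prob, 0.5)
  l2 <- law_from_hazards(list(time = c(1, 2), inc = c(0.25, 0.25)),
                         list(time = numeric(0), inc = numeric(0)), cens)
  expect_equal(l2$time_mass, c(0.25, 0.1875))
  expect_equal(l2$tail_mass, 0.5625)
})

test_that("build-law and law-from-hazards are exact inverses", {
  for (seed in c(3, 21)) {
    d <- random_crdata(120, seed)
    law <- suppressWarnings(empirical_law(d))
    law2 <- suppressWarnings(
      law_from_hazards(nelson_aalen(d, 1), nelson_aalen(d, 2),
                       kaplan_meier(d, "censoring")))
    expect_equal(law2$support, law$support)
    expect_equal(law2$time_mass, law$time_mass, tolerance = 1e-14)
    expect_equal(law2$tail_mass, law$tail_mass, tolerance = 1e-14)
    expect_equal(law2$type1_prob, law$type1_prob, tolerance = 1e-14)
  }
})

test_that("inadmissible pooled increments are an error naming the time", {
  cens <- list(support = 10, mass = 1)
  expect_error(law_from_hazards(list(time = 2, inc = 0.8),
                                list(time = 2, inc = 0.4), cens),
               "time 2", class = "crsim_law_error")
  # float slack just above 1 is clamped, not an error
  l <- law_from_hazards(list(time = 2, inc = 0.5),
                        list(time = 2, inc = 0.5 + 1e-10), cens)
  expect_equal(l$time_mass, 1)
  expect_equal(l$tail_mass, 0)
})

test_that("identity transform with zero betas is a fixed point", {
  d <- random_crdata(200, 77)
  laws <- suppressWarnings(apply_scenario(d, scenario(0, 0)))
  law <- suppressWarnings(empirical_law(d))
  expect_equal(laws$control$time_mass, law$time_mass, tolerance = 1e-14)
  expect_equal(laws$treatment$time_mass, law$time_mass, tolerance = 1e-14)
  expect_equal(laws$treatment$type1_prob, law$type1_prob, tolerance = 1e-14)
})

test_that("baseline transformations move cumulative hazards as intended", {
  d <- generate_fixture(calibrate_fixture(), n = 400, seed = 8)
  h1 <- nelson_aalen(d, 1)
  cum <- cumsum(h1$inc)
  expect_true(all(cum < 1))
  expect_true(all(cum^(1 / 4) > cum))   # root4 amplifies below 1
  expect_true(all(cum^2 < cum))         # square shrinks below 1
  # treatment effect beta1 < 0 lowers the cause-1 probability everywhere
  laws <- apply_scenario(d, scenario(beta1 = -0.4, beta2 = 0))
  shared <- laws$control$type1_prob > 0 & laws$control$type1_prob < 1
  expect_true(all(laws$treatment$type1_prob[shared] <
                    laws$control$type1_prob[shared]))
  expect_true(all(laws$treatment$type1_prob <= laws$control$type1_prob))
})

test_that("transform validation rejects maps that break the contract", {
  expect_error(scenario(0, 0, transform1 = function(x) x + 1),
               class = "crsim_validation_error")
  expect_error(scenario(0, 0, transform1 = function(x) -x),
               class = "crsim_validation_error")
  expect_error(scenario(0, 0, transform1 = "cubed"),
               class = "crsim_validation_error")
  s <- scenario(0, 0, transform1 = function(x) sqrt(x))
  expect_equal(s$transform1$fn(4), 2)
})

test_that("laws serialize to JSON and back", {
  d <- random_crdata(80, 5)
  law <- suppressWarnings(empirical_law(d))
  path <- withr::local_tempfile(fileext = ".json")
  write_law_json(law, path)
  back <- read_law_json(path)
  expect_equal(back$support, law$support)
  expect_equal(back$time_mass, law$time_mass)
  expect_equal(back$tail_mass, law$tail_mass)
  expect_equal(back$cens_mass, law$cens_mass)
  # corrupted mass vectors are refused on read
  bad <- law; bad$tail_mass <- bad$tail_mass + 0.2
  write_law_json(bad, path)
  expect_error(read_law_json(path), class = "crsim_law_error")
})
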