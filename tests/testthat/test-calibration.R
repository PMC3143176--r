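test_that("the positivity proxy equals a brute-force sliding window", {
  set.seed(6)
  ovi <- matrix(stats::runif(30) < 0.3, nrow = 10, ncol = 3)
  got <- ovitrap_positivity(ovi, window = 7)
  expect_equal(got$fraction, oracle_positivity(ovi, 7))
  got3 <- ovitrap_positivity(ovi, window = 3)
  expect_equal(got3$fraction, oracle_positivity(ovi, 3))
  expect_error(ovitrap_positivity(ovi, window = 0), "window")
})

test_that("positivity hits the boundary cases", {
  none <- matrix(FALSE, 14, 5)
  expect_true(all(ovitrap_positivity(none)$fraction == 0))
  once <- matrix(FALSE, 14, 5)
  once[1, ] <- TRUE  # every container oviposited on day 1
  frac <- ovitrap_positivity(once, window = 7)$fraction
  expect_equal(frac[1:7], rep(1, 7))
  expect_equal(frac[8:14], rep(0, 7))
})

test_that("weekly aggregation averages whole weeks and drops the remainder", {
  daily <- data.frame(day = 1:17, fraction = c(rep(0.5, 7), rep(1, 7), 0, 0, 0))
  wk <- weekly_positivity(daily)
  expect_equal(wk$fraction, c(0.5, 1))
})

test_that("a target equal to the current simulated shares is a fixed point", {
  sv <- generate_survey_subset(survey_gen_params(3, 3), seed = 2)
  g <- build_replicated_grid(sv, 3, 3, n_copies = 1, seed = 1)
  w <- generate_weather(weather_regime("equatorial"), 200, seed = 4)
  p0 <- biology_params()
  sim <- aedespop:::simulate_type_shares(g, w, p0, replicates = 1,
                                         burn_in_days = 60, horizon = 140,
                                         seed = 10)
  target <- productivity_table(sim$share)
  cal <- calibrate_type_coefficients(g, w, target, p0, replicates = 1,
                                     tol = 0.02, max_iter = 5,
                                     burn_in_days = 60, horizon = 140,
                                     seed = 10)
  expect_true(cal$converged)
  expect_equal(cal$n_iterations, 1)
  expect_equal(unname(cal$alpha), rep(1, 14))
  expect_equal(cal$F0, p0$F0)
})

test_that("raising one type's target never lowers its fitted coefficient", {
  sv <- generate_survey_subset(survey_gen_params(3, 3), seed = 2)
  g <- build_replicated_grid(sv, 3, 3, n_copies = 1, seed = 1)
  w <- generate_weather(weather_regime("equatorial"), 200, seed = 4)
  p0 <- biology_params()
  sim <- aedespop:::simulate_type_shares(g, w, p0, replicates = 1,
                                         burn_in_days = 60, horizon = 140,
                                         seed = 10)
  base <- as.numeric(sim$share)
  names(base) <- names(sim$share)
  bumped <- base
  bumped["tires"] <- bumped["tires"] + 0.15
  bumped <- bumped / sum(bumped)
  fit <- function(tgt) {
    calibrate_type_coefficients(g, w, productivity_table(tgt), p0,
                                replicates = 1, tol = 0.001, max_iter = 3,
                                burn_in_days = 60, horizon = 140,
                                seed = 10)$alpha[["tires"]]
  }
  expect_gte(fit(bumped), fit(base))
})

test_that("the zero-share guard caps the update instead of dividing by zero", {
  # no simulated pupae at all: shares are all zero, every ratio is capped
  sv <- tiny_survey(2, 2, types = "large tanks", volumes = 10)
  g <- build_replicated_grid(sv, 2, 2, n_copies = 1, seed = 1)
  w <- constant_weather(40, t_mean = 15)  # too cold: nothing hatches
  target <- generate_target_productivity(seed = 3)
  expect_error(
    calibrate_type_coefficients(
      g, w, target, biology_params(), replicates = 1, tol = 0.02,
      max_iter = 2, burn_in_days = 0, horizon = 40, seed = 1),
    "absent from the grid")
  # restrict the target to the present type: capped, finite updates
  tgt <- stats::setNames(numeric(14), container_types())
  tgt["large tanks"] <- 1
  tgt <- productivity_table(tgt)
  cal <- calibrate_type_coefficients(
    g, w, tgt, biology_params(), replicates = 1, tol = 0.02,
    max_iter = 2, burn_in_days = 0, horizon = 40, seed = 1)
  expect_true(all(is.finite(cal$alpha)))
  expect_false(cal$converged)
})

test_that("F0 search reproduces a fixed point and moves in the right direction", {
  sv <- generate_survey_subset(survey_gen_params(3, 3), seed = 12)
  g <- build_replicated_grid(sv, 3, 3, n_copies = 1, seed = 2)
  w <- generate_weather(weather_regime("equatorial"), 220, seed = 9)
  p0 <- biology_params()
  out <- run_simulation(g, w, p0, burn_in_days = 60, horizon = 160,
                        seed = 151)
  base_mean <- mean(ovitrap_positivity(out)$fraction)

  cal <- calibrate_overall_F0(g, w, base_mean, p0, tol = 0.03,
                              burn_in_days = 60, horizon = 160,
                              replicates = 1, seed = 50)
  expect_true(cal$converged)
  expect_lt(abs(cal$simulated_mean_positivity - base_mean), 0.03 + 1e-12)

  # a clearly higher target demands more food
  hi_target <- min(0.99, base_mean * 1.2)
  cal_hi <- calibrate_overall_F0(g, w, hi_target, p0, tol = 0.02,
                                 burn_in_days = 60, horizon = 160,
                                 replicates = 1, seed = 50)
  lo_target <- base_mean * 0.6
  cal_lo <- calibrate_overall_F0(g, w, lo_target, p0, tol = 0.02,
                                 burn_in_days = 60, horizon = 160,
                                 replicates = 1, seed = 50)
  expect_gt(cal_hi$multiplier, cal_lo$multiplier)
})

test_that("calibration leaves non-food biology untouched", {
  sv <- generate_survey_subset(survey_gen_params(3, 3), seed = 2)
  g <- build_replicated_grid(sv, 3, 3, n_copies = 1, seed = 1)
  w <- generate_weather(weather_regime("equatorial"), 150, seed = 4)
  p0 <- biology_params()
  tgt <- restrict_target_to_grid(generate_target_productivity(seed = 8), g)
  cal <- calibrate_type_coefficients(g, w, tgt, p0, replicates = 1,
                                     tol = 0.3, max_iter = 2,
                                     burn_in_days = 30, horizon = 100,
                                     seed = 6)
  skip_fields <- c("F0", "alpha", "beta")
  for (f in setdiff(names(p0), skip_fields)) {
    expect_identical(cal$params[[f]], p0[[f]])
  }
  expect_equal(cal$alpha[["large tanks"]], 1)
  expect_equal(cal$beta[["outside"]], 1)
})

test_that("productivity and positivity tables round-trip through CSV", {
  tab <- generate_target_productivity(seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_productivity(tab, path)
  tab2 <- read_productivity(path)
  expect_equal(as.numeric(tab2), as.numeric(tab), tolerance = 1e-12)

  pos <- generate_positivity_series("temperate", seed = 6)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_positivity(pos, path2)
  pos2 <- read_positivity(path2)
  expect_equal(pos2$fraction, pos$fraction, tolerance = 1e-12)
})
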