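test_that("daily food input is the product F0 * alpha * beta * V", {
  p <- biology_params(F0 = 0.5)
  expect_equal(daily_food_input("large tanks", "outside", 100, p), 50)
  p0 <- biology_params(F0 = 0)
  expect_equal(daily_food_input("tires", "inside", 30, p0), 0)
  alpha <- stats::setNames(rep(1, 14), container_types())
  alpha["plastic"] <- 2
  p2 <- biology_params(F0 = 0.1, alpha = alpha,
                       beta = c(inside = 0.5, outside = 1))
  expect_equal(daily_food_input("plastic", "inside", 10, p2), 1.0)
  # vectorized over containers
  expect_equal(daily_food_input(c("plastic", "large tanks"),
                                c("inside", "outside"), c(10, 100), p2),
               c(1.0, 10))
})

test_that("with no consumers the food pool follows input and decay", {
  sv <- tiny_survey(2, 2, types = "large tanks", volumes = 100)
  g <- build_replicated_grid(sv, 2, 2, n_copies = 1, seed = 1)
  p <- deterministic_params(inoculum_eggs = 0, inoculum_larvae = 0,
                            F0 = 0.5)
  out <- run_simulation(g, constant_weather(5), p, burn_in_days = 0,
                        horizon = 5, seed = 1, ledger = TRUE)
  led <- out$ledger
  f_in <- 0.5 * 100  # F0 * V, alpha = beta = 1
  delta <- p$food_decay_rate
  expect_equal(led$food_end[1, ], rep((0 + f_in) * (1 - delta), 4))
  expect_equal(led$food_end[2, ],
               rep((led$food_end[1, 1] + f_in) * (1 - delta), 4))
  expect_true(all(out$totals[, c("eggs", "larvae", "pupae", "adults")] == 0))
})

test_that("mature wet eggs do not hatch below the water-temperature gate", {
  sv <- tiny_survey(1, 2, types = "large tanks", volumes = 50)
  g <- build_replicated_grid(sv, 1, 2, n_copies = 1, seed = 1)
  p <- deterministic_params()  # min_hatch_water_temp = 22
  # outside containers, sun = 0: water temperature equals daily air mean
  cold <- constant_weather(10, t_mean = 21)
  out <- run_simulation(g, cold, p, burn_in_days = 0, horizon = 10,
                        seed = 1, ledger = TRUE)
  expect_true(all(out$ledger$egg_hatched == 0))
  expect_true(all(out$ledger$water_temp < 22))

  warm <- constant_weather(10, t_mean = 22)
  out2 <- run_simulation(g, warm, p, burn_in_days = 0, horizon = 10,
                         seed = 1, ledger = TRUE)
  expect_gt(sum(out2$ledger$egg_hatched), 0)
  # the whole mature inoculum hatches on day one at the gate temperature
  expect_equal(out2$ledger$egg_hatched[1, ], rep(p$inoculum_eggs, 2))
})

test_that("well-fed larvae pupate on the degree-day schedule", {
  sv <- tiny_survey(1, 2, types = "large tanks", volumes = 1000)
  g <- build_replicated_grid(sv, 1, 2, n_copies = 1, seed = 1)
  p <- deterministic_params(F0 = 100, inoculum_larvae = 0)  # food unlimited
  t_mean <- 27
  # horizon short enough that no second generation can reach pupation
  out <- run_simulation(g, constant_weather(10, t_mean), p,
                        burn_in_days = 0, horizon = 10, seed = 1,
                        ledger = TRUE)
  # eggs hatch on day 1; development then needs ceil(1 / (c * (T - T0)))
  # days, and the weight gate is satisfied earlier under full feeding
  dev_days <- ceiling(1 / (p$dev_rate_coeff * (t_mean - p$dev_temp_threshold)))
  growth_days <- ceiling(
    log(p$pupation_weight / p$initial_larval_weight) /
      log(1 + p$growth_efficiency * p$larval_intake_rate))
  expected_day <- max(dev_days, growth_days)
  pupation_days <- which(rowSums(out$ledger$larv_pupated) > 0)
  expect_equal(pupation_days, expected_day)
  expect_equal(sum(out$ledger$larv_pupated), 2 * p$inoculum_eggs)
})

test_that("unfed larvae starve and die once reserves are exhausted", {
  sv <- tiny_survey(1, 1, types = "large tanks", volumes = 100)
  g <- build_replicated_grid(sv, 1, 1, n_copies = 1, seed = 1)
  p <- deterministic_params(F0 = 0, inoculum_eggs = 0)
  out <- run_simulation(g, constant_weather(10), p, burn_in_days = 0,
                        horizon = 10, seed = 1)
  larv <- out$totals$larvae
  expect_equal(larv[1], 5)  # inoculum present, unfed
  expect_true(all(larv[(p$starvation_reserve_days + 2):10] == 0))
})

test_that("runs are bitwise-reproducible and extinction stays extinct", {
  sv <- tiny_survey(2, 3)
  g <- build_replicated_grid(sv, 2, 3, n_copies = 1, seed = 4)
  w <- generate_weather(weather_regime("equatorial"), 120, seed = 2)
  p <- biology_params()
  o1 <- run_simulation(g, w, p, burn_in_days = 30, horizon = 90, seed = 77)
  o2 <- run_simulation(g, w, p, burn_in_days = 30, horizon = 90, seed = 77)
  expect_identical(o1$totals, o2$totals)
  expect_identical(o1$oviposition, o2$oviposition)
  expect_identical(o1$pupae_by_house, o2$pupae_by_house)
  o3 <- run_simulation(g, w, p, burn_in_days = 30, horizon = 90, seed = 78)
  expect_false(identical(o1$totals, o3$totals))

  p0 <- biology_params(inoculum_eggs = 0, inoculum_larvae = 0,
                       adult_daily_survival = 0)
  o0 <- run_simulation(g, w, p0, burn_in_days = 0, horizon = 60, seed = 1)
  expect_true(all(o0$totals[, c("eggs", "larvae", "pupae", "adults")] == 0))
})

test_that("weather shorter than burn-in plus horizon is an error", {
  sv <- tiny_survey(1, 2)
  g <- build_replicated_grid(sv, 1, 2, n_copies = 1, seed = 1)
  expect_error(
    run_simulation(g, constant_weather(50), biology_params(),
                   burn_in_days = 40, horizon = 20, seed = 1),
    "too short")
})

test_that("crowding lowers per-capita pupation and delays development", {
  # one food-limited container; deterministic biology so the contrast is
  # exact rather than sampled
  sv <- tiny_survey(1, 1, types = "cans", volumes = 2)
  g <- build_replicated_grid(sv, 1, 1, n_copies = 1, seed = 1)
  run_with <- function(n0) {
    p <- deterministic_params(F0 = 0.5, inoculum_eggs = 0,
                              inoculum_larvae = n0,
                              starvation_reserve_days = 8)
    out <- run_simulation(g, constant_weather(60), p, burn_in_days = 0,
                          horizon = 60, seed = 5, ledger = TRUE)
    pup_by_day <- rowSums(out$ledger$larv_pupated)
    total <- sum(pup_by_day)
    mean_day <- if (total > 0) sum(seq_len(60) * pup_by_day) / total else NA
    list(per_capita = total / n0, mean_day = mean_day)
  }
  lo <- run_with(20)
  hi <- run_with(40)
  expect_lte(hi$per_capita, lo$per_capita)
  if (!is.na(lo$mean_day) && !is.na(hi$mean_day)) {
    expect_gte(hi$mean_day, lo$mean_day)
  }
})

test_that("oviposition site choice follows the V^(2/3) surface proxy", {
  volumes <- c(1, 8, 64)
  weights <- volumes^(2 / 3)
  probs <- weights / sum(weights)
  n <- 10000
  set.seed(31)
  counts <- aedespop:::oviposition_allocation(n, volumes)
  expect_equal(sum(counts), n)
  for (k in 1:3) {
    se <- sqrt(n * probs[k] * (1 - probs[k]))
    expect_lt(abs(counts[k] - n * probs[k]), 4 * se)
  }
})

test_that("dispersal moves females at most one step and conserves them", {
  sv <- tiny_survey(4, 4)
  g <- build_replicated_grid(sv, 4, 4, n_copies = 1, seed = 1)
  st <- aedespop:::init_sim_state(g, biology_params())
  set.seed(9)
  for (rep in 1:20) {
    counts <- stats::rpois(16, 10)
    moved <- aedespop:::disperse_counts(counts, st$neighbors, 0.3)
    expect_equal(sum(moved), sum(counts))
    expect_true(all(moved >= 0))
  }
  # a lone occupied corner can only send females to its two neighbours
  counts <- numeric(16)
  corner <- which(g$houses$row == 0 & g$houses$col == 0)
  counts[corner] <- 1000
  moved <- aedespop:::disperse_counts(counts, st$neighbors, 0.5)
  occupied <- which(moved > 0)
  d <- manhattan_distance(g$houses$row[occupied], g$houses$col[occupied],
                          0, 0)
  expect_true(all(d <= 1))
})
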