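# Daily-step stochastic simulation of container water/food dynamics,
# immature cohorts, and house-level adult females on a rectangular grid.
#
# The biology is a deliberately compact cohort model: linear degree-day
# larval development above a temperature threshold, weight gain
# proportional to food ingested, food-mediated starvation, and
# binomial/multinomial stochastic survival, hatch, oviposition-site choice
# and dispersal drawn from a single seeded generator in fixed order so any
# run is exactly reproducible.

#' Biological and food-model parameters
#'
#' Bundles every tunable rate of the simulator.  The food input into a
#' container of type i at location j with volume V (liters) is
#' `F = F0 * alpha[i] * beta[j] * V` (mg liver-powder equivalent per day).
#' Only relative values of `alpha` across types and of `beta` across
#' locations matter, so the convention `alpha["large tanks"] = 1` and
#' `beta["outside"] = 1` is enforced.
#'
#' @param F0 Baseline food input (mg per liter per day).
#' @param alpha Named numeric vector over the 14 container types
#'   (dimensionless multipliers; `large tanks` entry must be 1).
#' @param beta Named numeric vector over `c(inside, outside)`
#'   (`outside` entry must be 1).
#' @param food_decay_rate Fraction of container food lost per day.
#' @param cadaver_conversion Fraction of dead immature biomass returned to
#'   the container food pool.
#' @param larval_intake_rate Maximum food intake (mg food per mg larva per
#'   day).
#' @param growth_efficiency Weight gain per unit food ingested (mg/mg).
#' @param initial_larval_weight Weight of a newly hatched larva (mg).
#' @param pupation_weight Minimum larval weight for pupation (mg).
#' @param min_hatch_water_temp Minimum water temperature for egg hatch
#'   (degrees C; default 22).
#' @param dev_rate_coeff Larval development accrued per degree-day above
#'   `dev_temp_threshold` (fraction of the larval stage per degree-day).
#' @param dev_temp_threshold Lower temperature threshold for development
#'   (degrees C).
#' @param egg_daily_survival,larva_daily_survival,pupa_daily_survival
#'   Baseline daily survival fractions of the immature stages.
#' @param dry_egg_survival Daily survival of mature eggs stranded in a dry
#'   container.
#' @param starvation_mortality_multiplier Factor applied to daily larval
#'   mortality while a cohort is starving.
#' @param starvation_reserve_days Days a cohort can starve before it dies
#'   outright (its metabolic reserves).
#' @param starvation_intake_fraction Fraction of the intake ceiling below
#'   which a cohort counts as starving that day.
#' @param egg_maturation_days Days from oviposition to hatch-competence.
#' @param pupal_days Duration of the pupal stage (days).
#' @param gonotrophic_cycle_days Days from adult emergence (or previous
#'   oviposition) to the next oviposition.
#' @param eggs_per_batch Eggs laid per oviposition.
#' @param adult_daily_survival Daily survival of adult females.
#' @param female_fraction Fraction of emerging adults that are female
#'   (males are not tracked; females are assumed mated).
#' @param dispersal_prob Per-day probability that a female moves to a
#'   Manhattan-adjacent house.
#' @param water_sun_warming Water warming (degrees C) of a fully
#'   sun-exposed outside container over the daily mean air temperature.
#' @param water_inside_offset Water temperature offset for inside
#'   containers (degrees C).
#' @param rain_fill_efficiency Named vector `c(passive, assisted)`:
#'   fraction of container volume gained per mm of rain.
#' @param evaporation_rate Fraction of container volume lost to
#'   evaporation per day.
#' @param lid_factor Multiplier a lid applies to both rain gain and
#'   evaporative loss.
#' @param inoculum_eggs,inoculum_larvae Initial seeding of every
#'   container at day 0.
#' @return A list of class `biology_params`.
#' @export
biology_params <- function(F0 = 0.5,
                           alpha = NULL,
                           beta = NULL,
                           food_decay_rate = 0.1,
                           cadaver_conversion = 0.5,
                           larval_intake_rate = 1.0,
                           growth_efficiency = 0.5,
                           initial_larval_weight = 0.04,
                           pupation_weight = 1.0,
                           min_hatch_water_temp = 22,
                           dev_rate_coeff = 1 / 110,
                           dev_temp_threshold = 13.4,
                           egg_daily_survival = 0.99,
                           dry_egg_survival = 0.95,
                           larva_daily_survival = 0.97,
                           pupa_daily_survival = 0.99,
                           starvation_mortality_multiplier = 5,
                           starvation_reserve_days = 3,
                           starvation_intake_fraction = 0.25,
                           egg_maturation_days = 3,
                           pupal_days = 2,
                           gonotrophic_cycle_days = 4,
                           eggs_per_batch = 63,
                           adult_daily_survival = 0.89,
                           female_fraction = 0.5,
                           dispersal_prob = 0.05,
                           water_sun_warming = 3,
                           water_inside_offset = -1,
                           rain_fill_efficiency = c(passive = 0.005,
                                                    assisted = 0.02),
                           evaporation_rate = 0.05,
                           lid_factor = 0.5,
                           inoculum_eggs = 10,
                           inoculum_larvae = 5) {
  types <- container_types()
  if (is.null(alpha)) alpha <- stats::setNames(rep(1, 14), types)
  if (is.null(beta)) beta <- c(inside = 1, outside = 1)
  if (!all(types %in% names(alpha))) {
    stop("alpha must be named over all 14 container types")
  }
  if (!all(c("inside", "outside") %in% names(beta))) {
    stop("beta must be named over 'inside' and 'outside'")
  }
  alpha <- alpha[types]
  beta <- beta[c("inside", "outside")]
  if (abs(alpha[["large tanks"]] - 1) > 1e-9) {
    stop("normalization requires alpha['large tanks'] == 1")
  }
  if (abs(beta[["outside"]] - 1) > 1e-9) {
    stop("normalization requires beta['outside'] == 1")
  }
  fracs <- c(food_decay_rate, cadaver_conversion, growth_efficiency,
             egg_daily_survival, dry_egg_survival, larva_daily_survival,
             pupa_daily_survival, adult_daily_survival, female_fraction,
             dispersal_prob, evaporation_rate, lid_factor)
  if (any(fracs < 0 | fracs > 1)) stop("rate/fraction parameter out of [0, 1]")
  if (F0 < 0 || any(alpha < 0) || any(beta < 0)) {
    stop("food coefficients must be >= 0")
  }
  p <- as.list(environment())
  p$types <- NULL
  p$fracs <- NULL
  class(p) <- "biology_params"
  p
}

#' Daily food input into a container
#'
#' Implements the multiplicative food model
#' `F = F0 * alpha[type] * beta[location] * V`.
#'
#' @param type Container type label(s) (one of the 14 categories).
#' @param location `"inside"` or `"outside"` (vectorized).
#' @param volume_l Container volume(s) in liters.
#' @param params A `biology_params` object.
#' @return Food input in mg/day (vectorized).
#' @export
daily_food_input <- function(type, location, volume_l, params) {
  stopifnot(inherits(params, "biology_params"))
  if (!all(type %in% container_types())) stop("unknown container type")
  if (!all(location %in% c("inside", "outside"))) stop("unknown location")
  params$F0 * unname(params$alpha[type]) * unname(params$beta[location]) *
    volume_l
}

# --- internal state ---------------------------------------------------------
# Containers are columns of flat vectors; larval and pupal cohorts are
# parallel vectors appended/filtered daily; adults are per-house vectors
# plus an age-within-cycle matrix for pre-gravid females.

init_sim_state <- function(grid, params) {
  cont <- grid$containers
  houses <- grid$houses
  n_cont <- nrow(cont)
  n_house <- nrow(houses)
  cell_of <- match(cont$cell, houses$cell)

  loc_idx <- ifelse(cont$location == "inside", 1L, 2L)
  temp_offset <- ifelse(loc_idx == 2L,
                        params$water_sun_warming * cont$sun,
                        params$water_inside_offset)
  fill_idx <- match(cont$fill, fill_methods())
  rain_eff <- c(0, params$rain_fill_efficiency[["passive"]],
                params$rain_fill_efficiency[["assisted"]])[fill_idx]
  lid_mult <- ifelse(cont$lid > 0, params$lid_factor, 1)

  food_in <- daily_food_input(cont$type, cont$location, cont$volume_l, params)

  egg_rows <- params$egg_maturation_days + 1L  # last row = mature pool
  st <- new.env(parent = emptyenv())
  st$n_cont <- n_cont
  st$n_house <- n_house
  st$house_of <- cell_of                      # container -> house index
  st$type_idx <- match(cont$type, container_types())
  st$V <- cont$volume_l
  st$temp_offset <- temp_offset
  st$rain_eff <- rain_eff
  st$lid_mult <- lid_mult
  st$manual <- fill_idx == 1L
  st$food_in <- food_in
  st$water <- cont$volume_l                   # containers start full
  st$food <- numeric(n_cont)
  st$eggs <- matrix(0, nrow = egg_rows, ncol = n_cont)
  st$eggs[egg_rows, ] <- params$inoculum_eggs # mature, ready to hatch
  st$lv_cont <- integer(0)                    # larval cohorts
  st$lv_n <- numeric(0)
  st$lv_w <- numeric(0)
  st$lv_dev <- numeric(0)
  st$lv_starv <- integer(0)
  if (params$inoculum_larvae > 0) {
    st$lv_cont <- seq_len(n_cont)
    st$lv_n <- rep(params$inoculum_larvae, n_cont)
    st$lv_w <- rep(params$initial_larval_weight * 5, n_cont)
    st$lv_dev <- rep(0.2, n_cont)
    st$lv_starv <- rep(0L, n_cont)
  }
  st$pu_cont <- integer(0)                    # pupal cohorts
  st$pu_n <- numeric(0)
  st$pu_age <- integer(0)
  st$pre <- matrix(0, nrow = params$gonotrophic_cycle_days, ncol = n_house)
  st$gravid <- numeric(n_house)

  # neighbour lists for dispersal (Manhattan-adjacent cells)
  st$neighbors <- neighbor_list(houses, grid$n_rows, grid$n_cols)
  st
}

neighbor_list <- function(houses, n_rows, n_cols) {
  key <- houses$row * n_cols + houses$col
  idx_of <- integer(n_rows * n_cols)
  idx_of[key + 1L] <- seq_len(nrow(houses))
  lapply(seq_len(nrow(houses)), function(i) {
    r <- houses$row[i]; cc <- houses$col[i]
    nb <- integer(0)
    if (r > 0L)          nb <- c(nb, idx_of[(r - 1L) * n_cols + cc + 1L])
    if (r < n_rows - 1L) nb <- c(nb, idx_of[(r + 1L) * n_cols + cc + 1L])
    if (cc > 0L)         nb <- c(nb, idx_of[r * n_cols + cc])
    if (cc < n_cols - 1L) nb <- c(nb, idx_of[r * n_cols + cc + 2L])
    nb[nb > 0L]
  })
}

# Sum `values` over container index into a vector of length n.
sum_by <- function(values, index, n) {
  out <- numeric(n)
  if (length(values) > 0L) {
    s <- rowsum(values, index)
    out[as.integer(rownames(s))] <- s
  }
  out
}

# One simulated day.  Fixed event order: water & temperature update; food
# input then decay; egg survival/maturation/hatch; larval feeding, growth,
# starvation, mortality, pupation; cadaver return; pupal survival &
# emergence; adult survival, gonotrophic progression, oviposition;
# dispersal.  Returns per-day record components.
step_day <- function(st, t_min, t_max, rainfall, params,
                     ledger = NULL, d = NA_integer_) {
  n_cont <- st$n_cont

  # -- water temperature and volume
  tmean <- (t_min + t_max) / 2
  wtemp <- tmean + st$temp_offset
  gain <- rainfall * st$rain_eff * st$lid_mult * st$V
  loss <- params$evaporation_rate * st$lid_mult * st$V
  st$water <- ifelse(st$manual, st$V,
                     pmax(0, pmin(st$V, st$water + gain) - loss))
  wet <- st$water > 0

  # -- food: input then decay
  food_begin <- st$food
  after_input <- st$food + st$food_in
  decay <- after_input * params$food_decay_rate
  avail <- after_input - decay

  # -- eggs: survival (wet/dry), maturation, hatch
  egg_begin <- sum(st$eggs)
  egg_begin_c <- colSums(st$eggs)
  er <- nrow(st$eggs)
  surv_imm <- params$egg_daily_survival          # immature (embryonating) rows
  surv_mat <- ifelse(wet, params$egg_daily_survival, params$dry_egg_survival)
  ev <- as.vector(st$eggs)
  probs <- matrix(rep(surv_imm, er * n_cont), nrow = er)
  probs[er, ] <- surv_mat
  survivors <- stats::rbinom(er * n_cont, as.integer(ev), as.vector(probs))
  E <- matrix(as.numeric(survivors), nrow = er)
  egg_dead_c <- egg_begin_c - colSums(E)
  # maturation: shift ages up by one day; final row is an absorbing pool
  E2 <- matrix(0, nrow = er, ncol = n_cont)
  E2[er, ] <- E[er, ] + E[er - 1L, ]
  if (er > 2L) E2[2L:(er - 1L), ] <- E[1L:(er - 2L), ]
  hatch_ok <- wet & (wtemp >= params$min_hatch_water_temp)
  hatched_c <- ifelse(hatch_ok, E2[er, ], 0)
  E2[er, ] <- E2[er, ] - hatched_c
  st$eggs <- E2
  larv_begin_c <- sum_by(st$lv_n, st$lv_cont, n_cont)  # before today's hatch
  hatch_idx <- which(hatched_c > 0)
  if (length(hatch_idx) > 0L) {
    st$lv_cont <- c(st$lv_cont, hatch_idx)
    st$lv_n <- c(st$lv_n, hatched_c[hatch_idx])
    st$lv_w <- c(st$lv_w, rep(params$initial_larval_weight,
                              length(hatch_idx)))
    st$lv_dev <- c(st$lv_dev, rep(0, length(hatch_idx)))
    st$lv_starv <- c(st$lv_starv, rep(0L, length(hatch_idx)))
  }

  # -- larvae: feeding, growth, development, starvation, mortality, pupation
  consumption <- numeric(n_cont)
  cadaver <- numeric(n_cont)
  pup_new_c <- numeric(n_cont)
  larv_dead_c <- numeric(n_cont)
  if (length(st$lv_n) > 0L) {
    demand <- params$larval_intake_rate * st$lv_w * st$lv_n
    dem_c <- sum_by(demand, st$lv_cont, n_cont)
    fed_frac <- ifelse(dem_c > 0, pmin(1, avail / pmax(dem_c, 1e-300)), 1)
    intake <- demand * fed_frac[st$lv_cont]
    consumption <- pmin(avail, dem_c)
    per_larva <- ifelse(st$lv_n > 0, intake / st$lv_n, 0)
    st$lv_w <- st$lv_w + params$growth_efficiency * per_larva

    cohort_fed <- fed_frac[st$lv_cont]
    starving <- cohort_fed < params$starvation_intake_fraction
    st$lv_starv <- ifelse(starving, st$lv_starv + 1L, 0L)

    wt_l <- wtemp[st$lv_cont]
    st$lv_dev <- st$lv_dev + params$dev_rate_coeff *
      pmax(0, wt_l - params$dev_temp_threshold)

    mort <- 1 - params$larva_daily_survival
    mort <- ifelse(starving,
                   pmin(1, mort * params$starvation_mortality_multiplier),
                   mort)
    exhausted <- st$lv_starv > params$starvation_reserve_days
    mort[exhausted] <- 1
    deaths <- stats::rbinom(length(st$lv_n), as.integer(st$lv_n), mort)
    cadaver <- sum_by(deaths * st$lv_w * params$cadaver_conversion,
                      st$lv_cont, n_cont)
    larv_dead_c <- sum_by(as.numeric(deaths), st$lv_cont, n_cont)
    st$lv_n <- st$lv_n - deaths

    pupate <- st$lv_dev >= 1 & st$lv_w >= params$pupation_weight & st$lv_n > 0
    if (any(pupate)) {
      pup_new_c <- sum_by(st$lv_n[pupate], st$lv_cont[pupate], n_cont)
      st$pu_cont <- c(st$pu_cont, st$lv_cont[pupate])
      st$pu_n <- c(st$pu_n, st$lv_n[pupate])
      st$pu_age <- c(st$pu_age, rep(0L, sum(pupate)))
    }
    keep <- st$lv_n > 0 & !pupate
    st$lv_cont <- st$lv_cont[keep]
    st$lv_n <- st$lv_n[keep]
    st$lv_w <- st$lv_w[keep]
    st$lv_dev <- st$lv_dev[keep]
    st$lv_starv <- st$lv_starv[keep]
  }
  st$food <- pmax(0, avail - consumption) + cadaver

  # -- pupae: survival, aging, emergence
  # standing pupae at day start = current pool minus today's pupations
  pup_begin_c_pre <- sum_by(st$pu_n, st$pu_cont, n_cont) - pup_new_c
  pup_dead_c <- numeric(n_cont)
  emerged_c <- numeric(n_cont)
  if (length(st$pu_n) > 0L) {
    deaths <- stats::rbinom(length(st$pu_n), as.integer(st$pu_n),
                            1 - params$pupa_daily_survival)
    pup_dead_c <- sum_by(as.numeric(deaths), st$pu_cont, n_cont)
    st$pu_n <- st$pu_n - deaths
    st$pu_age <- st$pu_age + 1L
    emerge <- st$pu_age >= params$pupal_days & st$pu_n > 0
    if (any(emerge)) {
      emerged_c <- sum_by(st$pu_n[emerge], st$pu_cont[emerge], n_cont)
      females <- stats::rbinom(sum(emerge), as.integer(st$pu_n[emerge]),
                               params$female_fraction)
      fem_h <- sum_by(as.numeric(females), st$house_of[st$pu_cont[emerge]],
                      st$n_house)
      st$pre[1L, ] <- st$pre[1L, ] + fem_h
    }
    keep <- st$pu_n > 0 & !emerge
    st$pu_cont <- st$pu_cont[keep]
    st$pu_n <- st$pu_n[keep]
    st$pu_age <- st$pu_age[keep]
  }

  # -- adults: survival, gonotrophic progression, oviposition
  gono <- params$gonotrophic_cycle_days
  pre_v <- as.vector(st$pre)
  pre_surv <- stats::rbinom(length(pre_v), as.integer(pre_v),
                            params$adult_daily_survival)
  st$pre <- matrix(as.numeric(pre_surv), nrow = gono)
  st$gravid <- as.numeric(stats::rbinom(st$n_house, as.integer(st$gravid),
                                        params$adult_daily_survival))
  # advance the cycle: the oldest pre-gravid class becomes gravid
  newly_gravid <- st$pre[gono, ]
  if (gono > 1L) {
    st$pre[2L:gono, ] <- st$pre[1L:(gono - 1L), ]
  }
  st$pre[1L, ] <- 0
  st$gravid <- st$gravid + newly_gravid

  ovi_c <- numeric(n_cont)
  wet_by_house <- split(which(wet), st$house_of[wet])
  active <- which(st$gravid > 0)
  for (h in active) {
    wc <- wet_by_house[[as.character(h)]]
    if (is.null(wc) || length(wc) == 0L) next   # no site: stay gravid
    g <- st$gravid[h]
    counts <- oviposition_allocation(g, st$V[wc])
    ovi_c[wc] <- ovi_c[wc] + counts
    st$eggs[1L, wc] <- st$eggs[1L, wc] + counts * params$eggs_per_batch
    st$gravid[h] <- 0
    st$pre[1L, h] <- st$pre[1L, h] + g        # restart the cycle
  }
  laid_c <- ovi_c * params$eggs_per_batch

  # -- dispersal (each female moves at most one grid step per day)
  if (params$dispersal_prob > 0) {
    st$gravid <- disperse_counts(st$gravid, st$neighbors,
                                 params$dispersal_prob)
    for (r in seq_len(gono)) {
      st$pre[r, ] <- disperse_counts(st$pre[r, ], st$neighbors,
                                     params$dispersal_prob)
    }
  }

  larv_end_c <- sum_by(st$lv_n, st$lv_cont, n_cont)
  pup_end_c <- sum_by(st$pu_n, st$pu_cont, n_cont)

  if (!is.null(ledger)) {
    ledger$food_begin[d, ] <- food_begin
    ledger$food_input[d, ] <- st$food_in
    ledger$food_decay[d, ] <- decay
    ledger$food_consumed[d, ] <- consumption
    ledger$food_cadaver[d, ] <- cadaver
    ledger$food_end[d, ] <- st$food
    ledger$water_temp[d, ] <- wtemp
    ledger$egg_begin[d, ] <- egg_begin_c
    ledger$egg_laid[d, ] <- laid_c
    ledger$egg_hatched[d, ] <- hatched_c
    ledger$egg_dead[d, ] <- egg_dead_c
    ledger$egg_end[d, ] <- colSums(st$eggs)
    ledger$larv_begin[d, ] <- larv_begin_c
    ledger$larv_hatched[d, ] <- hatched_c
    ledger$larv_pupated[d, ] <- pup_new_c
    ledger$larv_dead[d, ] <- larv_dead_c
    ledger$larv_end[d, ] <- larv_end_c
    ledger$pup_begin[d, ] <- pup_begin_c_pre
    ledger$pup_in[d, ] <- pup_new_c
    ledger$pup_emerged[d, ] <- emerged_c
    ledger$pup_dead[d, ] <- pup_dead_c
    ledger$pup_end[d, ] <- pup_end_c
  }

  list(
    eggs = sum(st$eggs),
    larvae = sum(st$lv_n),
    pupae = sum(st$pu_n),
    adults = sum(st$pre) + sum(st$gravid),
    pupae_by_house = sum_by(pup_new_c, st$house_of, st$n_house),
    pup_new_c = pup_new_c,
    ovi = ovi_c > 0,
    hatched = sum(hatched_c)
  )
}

# Multinomial allocation of gravid females among the wet containers of a
# house: selection probability proportional to a water-surface proxy,
# V^(2/3).
oviposition_allocation <- function(n_females, volumes) {
  if (length(volumes) == 1L) return(n_females)
  as.vector(stats::rmultinom(1L, n_females, volumes^(2 / 3)))
}

# Binomial out-migration, multinomial allocation among grid neighbours.
disperse_counts <- function(counts, neighbors, prob) {
  src <- which(counts > 0)
  if (length(src) == 0L) return(counts)
  movers <- stats::rbinom(length(src), as.integer(counts[src]), prob)
  for (k in seq_along(src)) {
    m <- movers[k]
    if (m == 0L) next
    h <- src[k]
    nb <- neighbors[[h]]
    counts[h] <- counts[h] - m
    if (length(nb) == 1L) {
      counts[nb] <- counts[nb] + m
    } else {
      alloc <- as.vector(stats::rmultinom(1L, m, rep(1, length(nb))))
      counts[nb] <- counts[nb] + alloc
    }
  }
  counts
}

#' Run the container-resolution population simulation
#'
#' Initializes every container with a small egg and larva inoculum, then
#' iterates the daily loop (container food/water and immature dynamics,
#' house-level adult dynamics and oviposition, dispersal between
#' Manhattan-adjacent houses).  The first `burn_in_days` days are run but
#' excluded from all reported output.  Output is an exact function of
#' `(grid, weather, params, seed)`.
#'
#' @param grid A `sim_grid` from [build_replicated_grid()].
#' @param weather A `weather_series` at least `burn_in_days + horizon`
#'   days long.
#' @param params A `biology_params` object.
#' @param burn_in_days Days to discard before reporting (default 365).
#' @param horizon Reported days; defaults to all weather after burn-in.
#' @param seed Integer seed governing every stochastic draw.
#' @param ledger If `TRUE`, record the per-container-day food-balance and
#'   demographic ledger (memory-heavy; meant for audits on small grids).
#' @return A list of class `sim_output`: `totals` (data frame of per-day
#'   stage totals), `pupae_by_house` (days x houses matrix of pupations),
#'   `oviposition` (days x containers logical matrix), `pupae_by_container`
#'   (cumulative per container), `pupae_by_type` (cumulative per container
#'   type), `hatched_by_day`, and (if requested) `ledger`.
#' @export
run_simulation <- function(grid, weather, params, burn_in_days = 365,
                           horizon = NULL, seed = 1L, ledger = FALSE) {
  stopifnot(inherits(grid, "sim_grid"), inherits(params, "biology_params"))
  n_weather <- nrow(weather)
  if (is.null(horizon)) horizon <- n_weather - burn_in_days
  if (horizon < 1) stop("horizon must be >= 1")
  n_days <- burn_in_days + horizon
  if (n_weather < n_days) {
    stop("weather series too short: need ", n_days, " days, have ", n_weather)
  }

  rng <- local_rng(seed)
  on.exit(rng$restore())

  st <- init_sim_state(grid, params)
  n_cont <- st$n_cont
  n_house <- st$n_house

  led <- NULL
  if (ledger) {
    led <- new.env(parent = emptyenv())
    nm <- c("food_begin", "food_input", "food_decay", "food_consumed",
            "food_cadaver", "food_end", "water_temp",
            "egg_begin", "egg_laid", "egg_hatched", "egg_dead", "egg_end",
            "larv_begin", "larv_hatched", "larv_pupated", "larv_dead",
            "larv_end", "pup_begin", "pup_in", "pup_emerged", "pup_dead",
            "pup_end")
    for (v in nm) assign(v, matrix(0, n_days, n_cont), envir = led)
  }

  totals <- matrix(0, horizon, 4,
                   dimnames = list(NULL, c("eggs", "larvae", "pupae",
                                           "adults")))
  pupae_by_house <- matrix(0, horizon, n_house)
  ovi <- matrix(FALSE, horizon, n_cont)
  pup_cont_cum <- numeric(n_cont)
  hatched_by_day <- numeric(horizon)

  w_tmin <- weather$t_min
  w_tmax <- weather$t_max
  w_rain <- weather$rainfall

  for (t in seq_len(n_days)) {
    rec <- step_day(st, w_tmin[t], w_tmax[t], w_rain[t], params,
                    ledger = led, d = t)
    if (t > burn_in_days) {
      r <- t - burn_in_days
      totals[r, ] <- c(rec$eggs, rec$larvae, rec$pupae, rec$adults)
      pupae_by_house[r, ] <- rec$pupae_by_house
      ovi[r, ] <- rec$ovi
      pup_cont_cum <- pup_cont_cum + rec$pup_new_c
      hatched_by_day[r] <- rec$hatched
    }
  }

  pup_type <- stats::setNames(numeric(14), container_types())
  agg <- sum_by(pup_cont_cum, st$type_idx, 14L)
  pup_type[] <- agg

  out <- list(
    totals = data.frame(day = seq_len(horizon), totals),
    pupae_by_house = pupae_by_house,
    oviposition = ovi,
    pupae_by_container = pup_cont_cum,
    pupae_by_type = pup_type,
    hatched_by_day = hatched_by_day,
    grid = grid,
    params = params,
    burn_in_days = burn_in_days,
    seed = seed
  )
  if (ledger) out$ledger <- as.list(led)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Simulation output:", nrow(x$totals), "reported days,",
      ncol(x$pupae_by_house), "houses,", ncol(x$oviposition),
      "containers\n")
  cat("  cumulative pupae:", sum(x$pupae_by_container), "\n")
  invisible(x)
}

#' Write simulation output tables
#'
#' Writes the per-day stage totals, the days x houses pupation matrix, the
#' per-container oviposition indicator matrix, and a run-metadata JSON
#' (parameters and seed) into a directory.
#'
#' @param output A `sim_output`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(output, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(output$totals, file.path(dir, "stage_totals.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(output$pupae_by_house),
                   file.path(dir, "pupae_by_house.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(output$oviposition * 1L),
                   file.path(dir, "oviposition.csv"), row.names = FALSE)
  meta <- list(
    seed = output$seed,
    burn_in_days = output$burn_in_days,
    params = unclass(output$params)
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
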