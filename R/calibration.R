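# Calibration of the food-input coefficients: iterative damped
# multiplicative adjustment of the per-type coefficients against a target
# pupal-productivity distribution, and a scalar bracketed search on the
# baseline F0 against an ovitrap-positivity target.

#' Productivity table constructor / validator
#'
#' Shares of total pupal production attributed to each of the 14 container
#' types; must be non-negative and sum to 1.
#'
#' @param share Named numeric vector over the 14 container types.
#' @return A named numeric vector of class `productivity_table`.
#' @export
productivity_table <- function(share) {
  types <- container_types()
  if (!all(types %in% names(share))) {
    stop("productivity table must name all 14 container types")
  }
  share <- share[types]
  if (any(share < 0)) stop("shares must be >= 0")
  if (abs(sum(share) - 1) > 1e-9) stop("shares must sum to 1")
  class(share) <- "productivity_table"
  share
}

#' Restrict a productivity target to the types present on a grid
#'
#' Container types absent from a grid cannot produce pupae, so a target
#' that gives them positive share is unattainable there.  This projects
#' the target onto the types the grid holds and renormalizes; the removed
#' mass is spread proportionally over the remaining types.
#'
#' @param target A `productivity_table`.
#' @param grid A `sim_grid`.
#' @return A `productivity_table` with zero share on absent types.
#' @export
restrict_target_to_grid <- function(target, grid) {
  target <- productivity_table(target)
  present <- container_types() %in% unique(grid$containers$type)
  share <- as.numeric(target)
  share[!present] <- 0
  if (sum(share) == 0) stop("no mass left on the types present in the grid")
  productivity_table(stats::setNames(share / sum(share), container_types()))
}

#' Read / write a productivity table (`type,share` CSV)
#' @param path File path.
#' @return For the reader, a `productivity_table`.
#' @export
read_productivity <- function(path) {
  x <- utils::read.csv(path)
  productivity_table(stats::setNames(x$share, x$type))
}

#' @rdname read_productivity
#' @param tab A `productivity_table`.
#' @export
write_productivity <- function(tab, path) {
  utils::write.csv(data.frame(type = names(tab), share = as.numeric(tab)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a weekly positivity series (`week,fraction[,lo,hi]` CSV)
#' @param path File path.
#' @return For the reader, a data frame with `week` and `fraction`.
#' @export
read_positivity <- function(path) {
  x <- utils::read.csv(path)
  if (any(x$fraction < 0 | x$fraction > 1)) {
    stop("positivity fractions must be in [0, 1]")
  }
  x
}

#' @rdname read_positivity
#' @param x Positivity data frame.
#' @export
write_positivity <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Ovitrap-positivity proxy from simulation output
#'
#' For each reported day, the fraction of containers that received at
#' least one oviposition within the trailing `window` days — the model
#' proxy for the weekly fraction of positive ovitraps in field
#' monitoring.
#'
#' @param output A `sim_output` (or a logical days x containers matrix of
#'   daily oviposition indicators).
#' @param window Trailing window length in days (default 7).
#' @return A data frame with columns `day` and `fraction`.
#' @export
ovitrap_positivity <- function(output, window = 7L) {
  if (window < 1) stop("window must be >= 1")
  ovi <- if (inherits(output, "sim_output")) output$oviposition else output
  n_days <- nrow(ovi)
  n_cont <- ncol(ovi)
  # trailing-window "any oviposition" via cumulative sums per container
  cs <- apply(ovi * 1L, 2, cumsum)
  cs <- rbind(0, cs)
  frac <- vapply(seq_len(n_days), function(t) {
    lo <- max(0L, t - window)
    sum(cs[t + 1L, ] - cs[lo + 1L, ] > 0) / n_cont
  }, numeric(1))
  data.frame(day = seq_len(n_days), fraction = frac)
}

#' Aggregate a daily positivity series to weeks
#'
#' @param daily Data frame from [ovitrap_positivity()].
#' @return Data frame with `week` and `fraction` (mean of the 7 daily
#'   values; a trailing partial week is dropped).
#' @export
weekly_positivity <- function(daily) {
  n_weeks <- nrow(daily) %/% 7L
  if (n_weeks < 1L) stop("need at least 7 days for a weekly series")
  wk <- rep(seq_len(n_weeks), each = 7L)
  frac <- tapply(daily$fraction[seq_len(n_weeks * 7L)], wk, mean)
  data.frame(week = seq_len(n_weeks), fraction = as.numeric(frac))
}

# Simulated per-type and per-location pupal shares, averaged over
# replicate runs.
simulate_type_shares <- function(grid, weather, params, replicates,
                                 burn_in_days, horizon, seed) {
  tot <- stats::setNames(numeric(14), container_types())
  loc <- c(inside = 0, outside = 0)
  grand <- 0
  inside <- grid$containers$location == "inside"
  for (r in seq_len(replicates)) {
    out <- run_simulation(grid, weather, params,
                          burn_in_days = burn_in_days, horizon = horizon,
                          seed = seed + r)
    tot <- tot + out$pupae_by_type
    loc <- loc + c(inside = sum(out$pupae_by_container[inside]),
                   outside = sum(out$pupae_by_container[!inside]))
    grand <- grand + sum(out$pupae_by_type)
  }
  if (grand == 0) {
    return(list(share = tot, location_share = loc, total = 0))
  }
  list(share = tot / grand, location_share = loc / grand,
       total = grand / replicates)
}

#' Calibrate the per-type food coefficients against a productivity target
#'
#' Iteratively adjusts the container-type coefficients `alpha_i` (and
#' optionally the location coefficients `beta_j` and the baseline `F0`)
#' so that the average per-type share of pupal production simulated on
#' `grid` matches `target`.  Each iteration runs `replicates` short
#' simulations, computes simulated shares from cumulative pupae, applies
#' the damped multiplicative update
#' `alpha_i <- alpha_i * (target_i / simulated_i)^eta` with the ratio
#' clamped to a multiplicative trust region, then restores the
#' normalization `alpha["large tanks"] = 1` (and `beta["outside"] = 1`).
#' Types simulated at zero share with a positive target take the capped
#' ratio, so the update never divides by zero.  A persistent increase of
#' the discrepancy over 5 consecutive iterations halves the step size.
#'
#' @param grid Calibration `sim_grid` (distinct from any evaluation grid).
#' @param weather A `weather_series`.
#' @param target A `productivity_table`.
#' @param params0 Starting `biology_params`.
#' @param replicates Simulations per iteration.
#' @param tol Convergence tolerance on `max |simulated_i - target_i|`.
#' @param max_iter Iteration cap.
#' @param eta Damping exponent of the multiplicative update.
#' @param burn_in_days,horizon Simulation span per replicate.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param target_location Optional length-2 named vector of
#'   inside/outside pupal shares to fit `beta` against (left fixed when
#'   `NULL`).
#' @param target_total Optional target for mean cumulative pupae per run,
#'   fit by scaling `F0` (left fixed when `NULL`).
#' @param ratio_cap Multiplicative trust region per iteration.
#' @return A list of class `calibration_result`: fitted `params`,
#'   `converged`, `n_iterations`, `trace` (per-iteration discrepancy),
#'   `simulated_share`, `target`.
#' @export
calibrate_type_coefficients <- function(grid, weather, target, params0,
                                        replicates = 5L, tol = 0.02,
                                        max_iter = 20L, eta = 0.5,
                                        burn_in_days = 180L, horizon = 365L,
                                        seed = 1L,
                                        target_location = NULL,
                                        target_total = NULL,
                                        ratio_cap = 4) {
  stopifnot(inherits(params0, "biology_params"))
  target <- productivity_table(target)
  present <- container_types() %in% unique(grid$containers$type)
  if (any(!present & as.numeric(target) > 0)) {
    stop("target gives positive share to type(s) absent from the grid: ",
         paste(container_types()[!present & as.numeric(target) > 0],
               collapse = ", "))
  }

  params <- params0
  trace <- numeric(0)
  converged <- FALSE
  increases <- 0L
  step <- eta
  sim_share <- NULL

  for (it in seq_len(max_iter)) {
    sim <- simulate_type_shares(grid, weather, params, replicates,
                                burn_in_days, horizon,
                                seed = seed + (it - 1L) * replicates)
    sim_share <- sim$share
    disc <- max(abs(sim_share[present] - as.numeric(target)[present]))
    trace <- c(trace, disc)
    if (disc <= tol) {
      converged <- TRUE
      break
    }
    if (it == max_iter) break
    if (it > 1L && disc > trace[it - 1L]) {
      increases <- increases + 1L
      if (increases >= 5L) {
        step <- step / 2
        increases <- 0L
        message("calibration discrepancy increasing; halving step to ", step)
      }
    } else {
      increases <- 0L
    }

    ratio <- ifelse(sim_share > 0, as.numeric(target) / sim_share, ratio_cap)
    ratio[as.numeric(target) == 0] <- 1 / ratio_cap  # push unused types down
    ratio <- pmin(ratio_cap, pmax(1 / ratio_cap, ratio))
    alpha <- params$alpha * ratio^step
    alpha <- alpha / alpha[["large tanks"]]

    beta <- params$beta
    if (!is.null(target_location)) {
      loc_sim <- sim$location_share
      r_loc <- ifelse(loc_sim > 0,
                      target_location[names(loc_sim)] / loc_sim, ratio_cap)
      r_loc <- pmin(ratio_cap, pmax(1 / ratio_cap, r_loc))
      beta <- beta * r_loc[names(beta)]^step
      beta <- beta / beta[["outside"]]
    }

    F0 <- params$F0
    if (!is.null(target_total) && sim$total > 0) {
      r0 <- pmin(ratio_cap, pmax(1 / ratio_cap, target_total / sim$total))
      F0 <- F0 * r0^step
    }

    params <- modify_food_coefficients(params, F0 = F0, alpha = alpha,
                                       beta = beta)
  }

  structure(list(
    params = params,
    F0 = params$F0,
    alpha = params$alpha,
    beta = params$beta,
    converged = converged,
    n_iterations = length(trace),
    trace = trace,
    simulated_share = sim_share,
    target = target,
    seed = seed
  ), class = "calibration_result")
}

# Rebuild biology_params with new food coefficients, all else untouched.
modify_food_coefficients <- function(params, F0 = params$F0,
                                     alpha = params$alpha,
                                     beta = params$beta) {
  params$F0 <- F0
  params$alpha <- alpha
  params$beta <- beta
  # re-check normalization invariants
  if (abs(alpha[["large tanks"]] - 1) > 1e-9 ||
      abs(beta[["outside"]] - 1) > 1e-9) {
    stop("food-coefficient normalization violated")
  }
  params
}

#' Calibrate the baseline food input against a positivity target
#'
#' Temperate-mode calibration: with the type and location coefficients
#' frozen, finds the scalar `F0` at which the simulated mean
#' ovitrap-positivity proxy matches the mean of the target weekly series.
#' Mean positivity is monotone non-decreasing in `F0` over the search
#' bracket, so a bracketed bisection is used; a non-bracketing initial
#' interval is widened geometrically up to a cap.
#'
#' @param grid A `sim_grid`.
#' @param weather A `weather_series`.
#' @param target Positivity data frame (`week`, `fraction`) or a single
#'   target mean fraction.
#' @param params0 Starting `biology_params` (donor coefficients).
#' @param tol Tolerance on the mean-positivity match.
#' @param max_iter Bisection iteration cap.
#' @param burn_in_days,horizon Simulation span.
#' @param replicates Replicate runs averaged per evaluation.
#' @param seed Base seed.
#' @param bracket Initial multiplicative bracket around `params0$F0`.
#' @param widen_cap Maximum total widening factor of the bracket.
#' @return A `calibration_result` with the fitted `F0` (and multiplier
#'   relative to the donor value), the evaluation trace, and the final
#'   simulated mean positivity.
#' @export
calibrate_overall_F0 <- function(grid, weather, target, params0,
                                 tol = 0.02, max_iter = 12L,
                                 burn_in_days = 120L, horizon = 365L,
                                 replicates = 1L, seed = 1L,
                                 bracket = c(0.25, 4), widen_cap = 256) {
  stopifnot(inherits(params0, "biology_params"))
  target_mean <- if (is.data.frame(target)) mean(target$fraction)
                 else as.numeric(target)
  if (target_mean < 0 || target_mean > 1) {
    stop("target mean positivity must be in [0, 1]")
  }

  eval_mean <- function(mult, k) {
    p <- modify_food_coefficients(params0, F0 = params0$F0 * mult)
    vals <- vapply(seq_len(replicates), function(r) {
      out <- run_simulation(grid, weather, p, burn_in_days = burn_in_days,
                            horizon = horizon, seed = seed + k * 100L + r)
      mean(ovitrap_positivity(out)$fraction)
    }, numeric(1))
    mean(vals)
  }

  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- eval_mean(lo, 0L)
  f_hi <- eval_mean(hi, 1L)
  trace <- data.frame(multiplier = c(lo, hi), positivity = c(f_lo, f_hi))
  widen <- 1
  while ((f_lo - target_mean) * (f_hi - target_mean) > 0 &&
         widen < widen_cap) {
    widen <- widen * 2
    if (f_hi < target_mean) {
      hi <- hi * 2
      f_hi <- eval_mean(hi, 1L + nrow(trace))
      trace <- rbind(trace, data.frame(multiplier = hi, positivity = f_hi))
    } else {
      lo <- lo / 2
      f_lo <- eval_mean(lo, 1L + nrow(trace))
      trace <- rbind(trace, data.frame(multiplier = lo, positivity = f_lo))
    }
  }
  if ((f_lo - target_mean) * (f_hi - target_mean) > 0) {
    stop("could not bracket the positivity target within the widening cap")
  }

  converged <- FALSE
  mid <- (lo + hi) / 2
  f_mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)   # geometric bisection on the multiplier
    f_mid <- eval_mean(mid, 10L + it)
    trace <- rbind(trace, data.frame(multiplier = mid, positivity = f_mid))
    if (abs(f_mid - target_mean) <= tol) {
      converged <- TRUE
      break
    }
    if (f_mid < target_mean) lo <- mid else hi <- mid
  }

  params <- modify_food_coefficients(params0, F0 = params0$F0 * mid)
  structure(list(
    params = params,
    F0 = params$F0,
    multiplier = mid,
    alpha = params$alpha,
    beta = params$beta,
    converged = converged,
    n_iterations = nrow(trace),
    trace = trace,
    simulated_mean_positivity = f_mid,
    target_mean_positivity = target_mean,
    seed = seed
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result: converged =", x$converged,
      "after", x$n_iterations, "iterations\n")
  cat("  F0 =", signif(x$F0, 4), "\n")
  invisible(x)
}

#' Write a calibration result (with full trace) to JSON
#' @param result A `calibration_result`.
#' @param path Output path.
#' @export
write_calibration <- function(result, path) {
  out <- list(
    F0 = result$F0,
    alpha = as.list(result$alpha),
    beta = as.list(result$beta),
    converged = result$converged,
    n_iterations = result$n_iterations,
    trace = result$trace,
    seed = result$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
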