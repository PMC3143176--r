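# End-to-end evaluation pipeline: the fully customized mode (survey-based
# grid, per-type calibration, replicate simulations, spatial statistics)
# and the weather-only mode (donor grid and coefficients, F0-only
# calibration against a positivity series, weekly overlay).

#' Assemble a pipeline run configuration
#'
#' All inputs may be file paths (the CSV dialects defined by the reader
#' functions) or in-memory objects; synthetic generation blocks fill in
#' whatever is not supplied.
#'
#' @param mode `"full-customization"` or `"weather-only"`.
#' @param weather A `weather_series`, a path, or a `weather_regime` to
#'   generate from.
#' @param survey Survey data frame or path (simulation set).
#' @param calibration_survey Survey data frame or path for the
#'   calibration set (distinct houses from `survey`).
#' @param target Productivity table or path (full-customization mode).
#' @param positivity Positivity series or path (weather-only mode).
#' @param donor_params Donor `biology_params` (weather-only mode:
#'   coefficients carried over from a prior full customization).
#' @param block_rows,block_cols Survey block dimensions.
#' @param n_copies Copies tiled into the evaluation grid.
#' @param burn_in_days,horizon Simulation span.
#' @param replicates Number of replicate evaluation simulations.
#' @param d_max Largest distance for spatial statistics.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for report tables.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("full-customization", "weather-only"),
                       weather = NULL, survey = NULL,
                       calibration_survey = NULL, target = NULL,
                       positivity = NULL, donor_params = NULL,
                       block_rows = 17L, block_cols = 9L, n_copies = 4L,
                       burn_in_days = 365L, horizon = 365L,
                       replicates = 20L, d_max = 10L, seed = 1L,
                       out_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

resolve_weather <- function(w, n_days, seed) {
  if (is.null(w)) w <- weather_regime("equatorial")
  if (inherits(w, "weather_regime")) {
    return(generate_weather(w, n_days, seed = seed))
  }
  if (is.character(w)) w <- read_weather(w)
  if (nrow(w) < n_days) {
    stop("weather series too short for burn-in + horizon")
  }
  w
}

resolve_survey <- function(s, p, seed) {
  if (is.null(s)) return(generate_survey_subset(p, seed = seed))
  if (is.character(s)) return(read_survey(s))
  validate_survey(s)
  s
}

#' Run the fully customized evaluation pipeline
#'
#' Builds a calibration grid and a distinct evaluation grid, calibrates
#' the per-type food coefficients on the calibration grid against the
#' target productivity table, runs replicate simulations on the
#' evaluation grid, and computes the spatial statistics (Moran's I per
#' replicate, L-increment profile, local-G cluster profile) on per-house
#' cumulative pupal production.  Houses used for calibration never
#' contribute counts to the reported statistics.
#'
#' @param config A `run_config` with `mode = "full-customization"`.
#' @param calib_replicates,calib_max_iter,calib_tol Calibration settings.
#' @return A list of class `evaluation_report`.
#' @export
run_full_customization <- function(config, calib_replicates = 3L,
                                   calib_max_iter = 10L, calib_tol = 0.02) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "full-customization") {
    stop("config mode must be 'full-customization'")
  }
  seed <- config$seed
  n_days <- config$burn_in_days + config$horizon
  weather <- resolve_weather(config$weather, n_days, seed = seed + 11L)

  gen_p <- survey_gen_params(n_rows = config$block_rows,
                             n_cols = config$block_cols)
  survey <- resolve_survey(config$survey, gen_p, seed = seed + 21L)
  calib_survey <- resolve_survey(config$calibration_survey, gen_p,
                                 seed = seed + 22L)
  if (is.null(config$calibration_survey)) {
    # synthetic calibration set: relabel so the calibration/simulation
    # house split is explicit and auditable
    calib_survey$house_id <- sub("^H", "K", calib_survey$house_id)
    calib_survey$container_id <- sub("^C", "D", calib_survey$container_id)
  }
  if (length(intersect(unique(survey$house_id),
                       unique(calib_survey$house_id))) > 0L) {
    stop("calibration and simulation sets must be disjoint house sets")
  }

  target <- config$target
  if (is.null(target)) {
    target <- generate_target_productivity(seed = seed + 31L)
  } else if (is.character(target)) {
    target <- read_productivity(target)
  }

  calib_grid <- build_replicated_grid(calib_survey, config$block_rows,
                                      config$block_cols, n_copies = 1L,
                                      seed = seed + 41L)
  eval_grid <- build_replicated_grid(survey, config$block_rows,
                                     config$block_cols,
                                     n_copies = config$n_copies,
                                     seed = seed + 42L)

  # a small calibration block may lack rare types; the attainable target
  # is its projection onto the types the block holds
  target_fit <- restrict_target_to_grid(target, calib_grid)

  params0 <- biology_params()
  calib <- calibrate_type_coefficients(
    calib_grid, weather, target_fit, params0,
    replicates = calib_replicates, tol = calib_tol,
    max_iter = calib_max_iter,
    burn_in_days = min(config$burn_in_days, 180L),
    horizon = min(config$horizon, 365L),
    seed = seed + 51L
  )
  if (!calib$converged) {
    warning("per-type calibration did not converge; report written with ",
            "converged = FALSE")
  }

  reps <- vector("list", config$replicates)
  moran_tab <- data.frame()
  type_tot <- stats::setNames(numeric(14), container_types())
  house_counts <- NULL
  for (r in seq_len(config$replicates)) {
    out <- run_simulation(eval_grid, weather, calib$params,
                          burn_in_days = config$burn_in_days,
                          horizon = config$horizon, seed = seed + 100L + r)
    counts <- colSums(out$pupae_by_house)
    cm <- count_map(eval_grid$houses$row, eval_grid$houses$col, counts)
    mi <- tryCatch(morans_i(cm, n_perm = 199L, seed = seed + 200L + r),
                   error = function(e) NULL)
    moran_tab <- rbind(moran_tab, data.frame(
      replicate = r,
      I = if (is.null(mi)) NA_real_ else mi$I,
      expected = -1 / (length(counts) - 1),
      z = if (is.null(mi)) NA_real_ else mi$z,
      p_value = if (is.null(mi)) NA_real_ else mi$p_value
    ))
    type_tot <- type_tot + out$pupae_by_type
    if (is.null(house_counts)) house_counts <- counts
    reps[[r]] <- list(totals = out$totals, pupae_by_house_total = counts)
  }

  # L and G profiles on the first replicate's count map (per-replicate
  # Moran table already summarizes across replicates)
  cm1 <- count_map(eval_grid$houses$row, eval_grid$houses$col, house_counts)
  l_prof <- tryCatch(
    l_statistics(cm1, d_max = config$d_max, n_perm = 199L,
                 seed = seed + 300L),
    error = function(e) NULL)
  cluster_prof <- tryCatch(
    cluster_size_profile(cm1, seq_len(config$d_max)),
    error = function(e) NULL)

  sim_share <- if (sum(type_tot) > 0) type_tot / sum(type_tot) else type_tot
  report <- structure(list(
    mode = "full-customization",
    calibration = calib,
    productivity_comparison = data.frame(
      type = container_types(),
      target = as.numeric(target),
      simulated = as.numeric(sim_share)
    ),
    moran = moran_tab,
    l_increments = l_prof,
    cluster_profile = cluster_prof,
    replicates = reps,
    grid = eval_grid,
    seed = seed
  ), class = "evaluation_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Run the weather-only evaluation pipeline
#'
#' Carries a donor grid and donor food coefficients over unchanged, swaps
#' in the local weather, calibrates only the baseline `F0` against the
#' target positivity series, then simulates replicates and overlays the
#' weekly ovitrap-positivity proxy on the target, reporting any weeks of
#' zero simulated positivity.
#'
#' @param config A `run_config` with `mode = "weather-only"`,
#'   `donor_params` set, and either `survey` (donor survey block) or
#'   nothing (synthetic donor block).
#' @param calib_tol,calib_max_iter Settings of the F0 search.
#' @return A list of class `evaluation_report`.
#' @export
run_weather_only <- function(config, calib_tol = 0.02,
                             calib_max_iter = 12L) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "weather-only") {
    stop("config mode must be 'weather-only'")
  }
  if (is.null(config$donor_params)) {
    stop("weather-only mode requires donor coefficients (donor_params)")
  }
  seed <- config$seed
  n_days <- config$burn_in_days + config$horizon
  weather <- resolve_weather(config$weather, n_days, seed = seed + 11L)

  gen_p <- survey_gen_params(n_rows = config$block_rows,
                             n_cols = config$block_cols)
  survey <- resolve_survey(config$survey, gen_p, seed = seed + 21L)
  grid <- build_replicated_grid(survey, config$block_rows,
                                config$block_cols,
                                n_copies = config$n_copies,
                                seed = seed + 42L)

  positivity <- config$positivity
  if (is.null(positivity)) {
    positivity <- generate_positivity_series("temperate",
                                             n_weeks = 52L,
                                             seed = seed + 31L)
  } else if (is.character(positivity)) {
    positivity <- read_positivity(positivity)
  }

  calib <- calibrate_overall_F0(
    grid, weather, positivity, config$donor_params,
    tol = calib_tol, max_iter = calib_max_iter,
    burn_in_days = config$burn_in_days, horizon = config$horizon,
    seed = seed + 51L
  )

  weekly <- NULL
  zero_weeks <- NULL
  for (r in seq_len(config$replicates)) {
    out <- run_simulation(grid, weather, calib$params,
                          burn_in_days = config$burn_in_days,
                          horizon = config$horizon, seed = seed + 100L + r)
    wp <- weekly_positivity(ovitrap_positivity(out))
    if (is.null(weekly)) {
      weekly <- data.frame(week = wp$week)
    }
    weekly[[paste0("rep", r)]] <- wp$fraction
  }
  rep_mat <- as.matrix(weekly[, -1, drop = FALSE])
  overlay <- data.frame(
    week = weekly$week,
    simulated_mean = rowMeans(rep_mat),
    simulated_lo = apply(rep_mat, 1, stats::quantile, probs = 0.025),
    simulated_hi = apply(rep_mat, 1, stats::quantile, probs = 0.975),
    target = positivity$fraction[seq_len(nrow(weekly))]
  )
  zero_weeks <- overlay$week[overlay$simulated_mean == 0]

  report <- structure(list(
    mode = "weather-only",
    calibration = calib,
    positivity_overlay = overlay,
    zero_positivity_weeks = zero_weeks,
    grid = grid,
    seed = seed
  ), class = "evaluation_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write report tables to a directory (CSV/JSON)
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(report$calibration)) {
    write_calibration(report$calibration, file.path(dir, "calibration.json"))
  }
  if (!is.null(report$productivity_comparison)) {
    utils::write.csv(report$productivity_comparison,
                     file.path(dir, "productivity_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$moran)) {
    utils::write.csv(report$moran, file.path(dir, "moran.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$l_increments)) {
    utils::write.csv(as.data.frame(report$l_increments),
                     file.path(dir, "l_increments.csv"), row.names = FALSE)
  }
  if (!is.null(report$cluster_profile)) {
    utils::write.csv(report$cluster_profile,
                     file.path(dir, "cluster_profile.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$positivity_overlay)) {
    utils::write.csv(report$positivity_overlay,
                     file.path(dir, "positivity_overlay.csv"),
                     row.names = FALSE)
  }
  meta <- list(mode = report$mode, seed = report$seed)
  jsonlite::write_json(meta, file.path(dir, "report_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (", x$mode, ")\n", sep = "")
  if (!is.null(x$moran)) {
    cat("  Moran's I over", nrow(x$moran), "replicates: mean",
        signif(mean(x$moran$I, na.rm = TRUE), 3), "\n")
  }
  if (!is.null(x$zero_positivity_weeks)) {
    cat("  weeks of zero simulated positivity:",
        length(x$zero_positivity_weeks), "\n")
  }
  invisible(x)
}
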