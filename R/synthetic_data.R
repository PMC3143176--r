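# Synthetic generators for every pipeline input: household container
# surveys on a rectangular block, target pupal-productivity tables, and
# weekly ovitrap-positivity series.  Defaults emulate the structure of an
# Amazonian-city survey block (17 x 9 houses holding 871 containers) but
# the per-type frequencies and volumes are explicitly synthetic
# plausibility choices, not reconstructions of any real survey.

#' Survey generator parameters
#'
#' @param n_rows,n_cols Block dimensions in houses (defaults 17 x 9).
#' @param target_container_total Exact number of containers generated
#'   across the block; defaults to the survey density of 871 containers
#'   per 153 houses scaled to the block area (871 exactly for the default
#'   17 x 9 block).
#' @param type_weights Named per-type frequency weights over the 14
#'   categories (normalized internally).
#' @param volume_meanlog Named per-type log-normal location parameter of
#'   container volume (liters).
#' @param volume_sdlog Log-normal scale parameter, shared across types.
#' @param indoor_fraction Probability a container is located inside.
#' @param fill_mix Named probabilities over
#'   `c(manual, passive-rain, assisted-rain)`.
#' @param lid_prob Probability a container has a lid.
#' @return A list of class `survey_gen_params`.
#' @export
survey_gen_params <- function(n_rows = 17L, n_cols = 9L,
                              target_container_total = NULL,
                              type_weights = NULL,
                              volume_meanlog = NULL,
                              volume_sdlog = 0.5,
                              indoor_fraction = 0.3,
                              fill_mix = c("manual" = 0.5,
                                           "passive-rain" = 0.35,
                                           "assisted-rain" = 0.15),
                              lid_prob = 0.2) {
  types <- container_types()
  if (is.null(target_container_total)) {
    target_container_total <- round(871 / 153 * n_rows * n_cols)
  }
  if (is.null(type_weights)) {
    type_weights <- stats::setNames(
      c(0.18, 0.12, 0.03, 0.08, 0.06, 0.07, 0.10, 0.07, 0.12, 0.04,
        0.08, 0.03, 0.01, 0.01), types)
  }
  if (is.null(volume_meanlog)) {
    volume_meanlog <- stats::setNames(
      log(c(20, 60, 200, 8, 10, 5, 5, 1, 0.5, 80, 0.3, 2, 300, 0.5)),
      types)
  }
  if (!all(types %in% names(type_weights))) {
    stop("type_weights must name all 14 container types")
  }
  if (any(type_weights < 0)) stop("type weights must be >= 0")
  if (sum(type_weights) <= 0) stop("type weights must not all be zero")
  type_weights <- type_weights[types] / sum(type_weights[types])
  if (!all(names(fill_mix) %in% fill_methods())) {
    stop("fill_mix must be named over the fill methods")
  }
  p <- list(n_rows = n_rows, n_cols = n_cols,
            target_container_total = target_container_total,
            type_weights = type_weights,
            volume_meanlog = volume_meanlog[types],
            volume_sdlog = volume_sdlog,
            indoor_fraction = indoor_fraction,
            fill_mix = fill_mix / sum(fill_mix),
            lid_prob = lid_prob)
  class(p) <- "survey_gen_params"
  p
}

#' Generate a synthetic household container survey block
#'
#' Produces exactly `n_rows * n_cols` houses on a rectangular block and
#' exactly `target_container_total` containers.  Container counts per
#' house are independent equal-rate Poisson draws conditioned on the
#' exact total (realized as a single multinomial draw, which is that
#' conditional law).  Container attributes are drawn from the stated
#' mixes; inside containers get zero sun exposure and outside containers
#' a uniform exposure fraction.
#'
#' @param p A `survey_gen_params`.
#' @param seed Integer seed; the same seed always yields the identical
#'   survey.
#' @return A validated survey data frame (see [validate_survey()]).
#' @export
generate_survey_subset <- function(p = survey_gen_params(), seed = 1L) {
  stopifnot(inherits(p, "survey_gen_params"))
  rng <- local_rng(seed)
  on.exit(rng$restore())

  n_houses <- p$n_rows * p$n_cols
  house_id <- sprintf("H%03d", seq_len(n_houses))
  rows <- (seq_len(n_houses) - 1L) %/% p$n_cols
  cols <- (seq_len(n_houses) - 1L) %% p$n_cols

  if (p$target_container_total < n_houses) {
    stop("need at least one container per house")
  }
  # one container guaranteed per house (a surveyed house holds at least
  # one water-filled container); remainder is equal-rate Poisson
  # conditioned on the exact total, i.e. a multinomial draw
  counts <- 1L + as.vector(
    stats::rmultinom(1L, p$target_container_total - n_houses,
                     rep(1, n_houses)))
  n_cont <- sum(counts)
  h_idx <- rep(seq_len(n_houses), counts)

  type <- sample(container_types(), n_cont, replace = TRUE,
                 prob = p$type_weights)
  location <- ifelse(stats::runif(n_cont) < p$indoor_fraction,
                     "inside", "outside")
  sun <- ifelse(location == "inside", 0, stats::runif(n_cont))
  lid <- as.integer(stats::runif(n_cont) < p$lid_prob)
  fill <- sample(names(p$fill_mix), n_cont, replace = TRUE,
                 prob = p$fill_mix)
  volume <- stats::rlnorm(n_cont, p$volume_meanlog[type], p$volume_sdlog)

  out <- data.frame(
    container_id = sprintf("C%05d", seq_len(n_cont)),
    house_id = house_id[h_idx],
    row = rows[h_idx],
    col = cols[h_idx],
    type = type,
    location = location,
    sun = sun,
    lid = lid,
    fill = fill,
    volume_l = round(volume, 3)
  )
  validate_survey(out)
  out
}

#' Generate a target pupal-productivity table
#'
#' Draws a 14-type share vector from a Dirichlet distribution.  With
#' `ordered = TRUE` the sorted shares are assigned to the canonical type
#' order, so productivity decreases from `plastic` down to `pet`.
#'
#' @param concentration Dirichlet concentration (scalar, or named
#'   per-type vector).
#' @param ordered Enforce the decreasing-productivity ordering.
#' @param seed Integer seed.
#' @return A `productivity_table`.
#' @export
generate_target_productivity <- function(concentration = 2, ordered = TRUE,
                                         seed = 1L) {
  types <- container_types()
  conc <- if (length(concentration) == 1L) rep(concentration, 14)
          else as.numeric(concentration[types])
  if (any(conc <= 0)) stop("concentration must be > 0")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  g <- stats::rgamma(14, shape = conc, rate = 1)
  share <- g / sum(g)
  if (ordered) share <- sort(share, decreasing = TRUE)
  productivity_table(stats::setNames(share, types))
}

#' Generate a synthetic weekly ovitrap-positivity series
#'
#' Temperate regime: positivity tracks a seasonal cycle that is zero
#' through the cold weeks (the series starts at mid-winter, so a
#' July-to-June reporting year puts the trough first) and rises to a
#' single broad summer peak.  Equatorial regime: high, weakly varying
#' positivity year-round.  Values are clamped to \[0, 1\].
#'
#' @param regime `"temperate"` or `"equatorial"`.
#' @param n_weeks Series length in weeks (>= 52).
#' @param noise Standard deviation of week-to-week Gaussian noise.
#' @param seed Integer seed.
#' @param peak Peak positivity of the temperate summer (or the equatorial
#'   level).
#' @return A data frame with columns `week` and `fraction`.
#' @export
generate_positivity_series <- function(regime = c("temperate", "equatorial"),
                                       n_weeks = 52L, noise = 0.03,
                                       seed = 1L, peak = 0.8) {
  regime <- match.arg(regime)
  if (n_weeks < 52L) stop("n_weeks must be >= 52")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  wk <- seq_len(n_weeks)
  if (regime == "temperate") {
    # seasonal signal in [-1, 1], minimum at week 0 (mid-winter start)
    season <- -cos(2 * pi * (wk - 1) / 52)
    base <- pmax(0, season - 0.3) / (1 - 0.3) * peak
  } else {
    season <- cos(2 * pi * (wk - 1) / 52)
    base <- peak * (0.9 + 0.1 * season)
  }
  frac <- pmin(1, pmax(0, base + stats::rnorm(n_weeks, 0, noise)))
  data.frame(week = wk, fraction = frac)
}
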