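# Daily weather series: ingestion, validation, and synthesis for the two
# climate regimes the simulator is exercised under (equatorial and temperate).

#' Validate a daily weather data frame
#'
#' Checks the invariants every day of a weather series must satisfy:
#' consecutive calendar dates with no gaps, `t_min <= t_max`, non-negative
#' rainfall, and relative humidity in \[0, 100\].
#'
#' @param x A data frame with columns `date` (`Date`), `t_min`, `t_max`
#'   (degrees C), `rainfall` (mm/day) and `rel_humidity` (percent).
#' @return `x` invisibly, with class `weather_series` prepended.
#' @export
validate_weather <- function(x) {
  required <- c("date", "t_min", "t_max", "rainfall", "rel_humidity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("weather series is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0L) stop("weather series is empty")
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("weather series contains unparseable dates")
  dd <- diff(as.integer(x$date))
  if (any(dd != 1L)) {
    i <- which(dd != 1L)[1L]
    if (dd[i] > 1L) {
      stop("gap in weather series: missing day after ", x$date[i],
           " (next record is ", x$date[i + 1L], ")")
    }
    stop("weather series dates are not strictly increasing at ", x$date[i])
  }
  bad <- which(x$t_min > x$t_max)
  if (length(bad) > 0L) {
    stop("t_min > t_max on ", x$date[bad[1L]])
  }
  if (any(x$rainfall < 0)) {
    stop("negative rainfall on ", x$date[which(x$rainfall < 0)[1L]])
  }
  if (any(x$rel_humidity < 0 | x$rel_humidity > 100)) {
    stop("relative humidity outside [0, 100] on ",
         x$date[which(x$rel_humidity < 0 | x$rel_humidity > 100)[1L]])
  }
  if (!inherits(x, "weather_series")) class(x) <- c("weather_series", class(x))
  invisible(x)
}

#' Read a daily weather series from a delimited text file
#'
#' Expects a comma-delimited file with header `date,tmin,tmax,rain,rh`, ISO
#' dates and one row per day.  The series is validated on read: any gap in
#' the calendar, a day with `tmin > tmax`, negative rain or out-of-range
#' humidity is an error naming the offending date.
#'
#' @param path Path to the weather file.
#' @return A `weather_series` data frame with columns `date`, `t_min`,
#'   `t_max`, `rainfall`, `rel_humidity`.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("weather file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("date", "tmin", "tmax", "rain", "rh")
  if (!all(expected %in% names(raw))) {
    stop("weather file must have header 'date,tmin,tmax,rain,rh'")
  }
  out <- data.frame(
    date = as.Date(raw$date),
    t_min = as.numeric(raw$tmin),
    t_max = as.numeric(raw$tmax),
    rainfall = as.numeric(raw$rain),
    rel_humidity = as.numeric(raw$rh)
  )
  validate_weather(out)
  class(out) <- c("weather_series", class(out))
  out
}

#' Write a weather series to the package's file dialect
#'
#' @param x A `weather_series` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(x, path) {
  out <- data.frame(
    date = format(as.Date(x$date), "%Y-%m-%d"),
    tmin = x$t_min, tmax = x$t_max, rain = x$rainfall, rh = x$rel_humidity
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Weather regime parameter sets
#'
#' Constructs the parameter list for the synthetic weather generator.  Two
#' presets are provided.  `"equatorial"` emulates an Amazonian climate:
#' year-round warm (mean daily maximum 32.2 degrees C, mean daily minimum
#' 21.4 degrees C, negligible seasonal amplitude) with frequent rain summing
#' to 2,878 mm per year.  `"temperate"` emulates a Southern-hemisphere
#' mid-latitude city with strong seasonality (coldest at mid-year, so that
#' week indices of a July-to-June reporting year put winter first).
#'
#' @param preset `"equatorial"`, `"temperate"`, or `"custom"`.
#' @param mean_t_max,mean_t_min Annual mean daily maximum/minimum
#'   temperature (degrees C).
#' @param amp_t_max,amp_t_min Seasonal (annual-cycle) amplitude of each
#'   (degrees C); 0 gives no seasonality.
#' @param sd_t_max,sd_t_min Standard deviation of day-to-day stochastic
#'   deviations (degrees C).
#' @param annual_rainfall Expected total rainfall per 365 days (mm).
#' @param rain_prob Probability that any given day is wet.
#' @param mean_rh Annual mean relative humidity (percent).
#' @param amp_rh Seasonal amplitude of relative humidity (percent).
#' @param sd_rh Day-to-day humidity noise (percent).
#' @param peak_doy Day of year at which temperature peaks (15 = mid January,
#'   the Southern-hemisphere summer used by the temperate preset).
#' @return A list of class `weather_regime`.
#' @export
weather_regime <- function(preset = c("equatorial", "temperate", "custom"),
                           mean_t_max = 32.2, mean_t_min = 21.4,
                           amp_t_max = 0, amp_t_min = 0,
                           sd_t_max = 1.8, sd_t_min = 1.2,
                           annual_rainfall = 2878, rain_prob = 0.6,
                           mean_rh = 85, amp_rh = 0, sd_rh = 4,
                           peak_doy = 15) {
  preset <- match.arg(preset)
  p <- switch(preset,
    equatorial = list(
      mean_t_max = 32.2, mean_t_min = 21.4,
      amp_t_max = 0.3, amp_t_min = 0.3,
      sd_t_max = 1.8, sd_t_min = 1.2,
      annual_rainfall = 2878, rain_prob = 0.6,
      mean_rh = 85, amp_rh = 0, sd_rh = 4,
      peak_doy = 15
    ),
    temperate = list(
      mean_t_max = 22.4, mean_t_min = 12.8,
      amp_t_max = 7.5, amp_t_min = 6.5,
      sd_t_max = 2.5, sd_t_min = 2.0,
      annual_rainfall = 1200, rain_prob = 0.25,
      mean_rh = 65, amp_rh = 10, sd_rh = 6,
      peak_doy = 15
    ),
    custom = list(
      mean_t_max = mean_t_max, mean_t_min = mean_t_min,
      amp_t_max = amp_t_max, amp_t_min = amp_t_min,
      sd_t_max = sd_t_max, sd_t_min = sd_t_min,
      annual_rainfall = annual_rainfall, rain_prob = rain_prob,
      mean_rh = mean_rh, amp_rh = amp_rh, sd_rh = sd_rh,
      peak_doy = peak_doy
    )
  )
  if (p$annual_rainfall < 0) stop("annual_rainfall must be >= 0")
  if (p$amp_t_max < 0 || p$amp_t_min < 0) stop("amplitudes must be >= 0")
  if (p$rain_prob <= 0 || p$rain_prob > 1) stop("rain_prob must be in (0, 1]")
  p$preset <- preset
  class(p) <- "weather_regime"
  p
}

#' Generate a synthetic daily weather series
#'
#' Daily maxima and minima follow a sinusoidal seasonal mean (period 365
#' days, peak at `peak_doy`) plus independent Gaussian day-to-day
#' deviations; the minimum is clamped below the maximum so the series
#' always satisfies `t_min <= t_max`.  Rain is a Bernoulli wet-day
#' indicator times an exponential depth whose mean is solved so that the
#' expected annual total equals `annual_rainfall`.  Relative humidity is
#' bounded seasonal noise around the regime mean.  The same seed always
#' yields the identical series.
#'
#' @param regime A `weather_regime` (see [weather_regime()]).
#' @param n_days Number of days to generate (>= 1).
#' @param seed Integer seed.
#' @param start_date First calendar date of the series.
#' @return A `weather_series` data frame.
#' @export
generate_weather <- function(regime, n_days, seed,
                             start_date = as.Date("2001-07-01")) {
  stopifnot(inherits(regime, "weather_regime"))
  if (n_days < 1) stop("n_days must be >= 1")
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(format(dates, "%j"))
  season <- cos(2 * pi * (doy - regime$peak_doy) / 365)

  rng <- local_rng(seed)
  on.exit(rng$restore())

  t_max <- regime$mean_t_max + regime$amp_t_max * season +
    stats::rnorm(n_days, 0, regime$sd_t_max)
  t_min <- regime$mean_t_min + regime$amp_t_min * season +
    stats::rnorm(n_days, 0, regime$sd_t_min)
  t_min <- pmin(t_min, t_max - 0.5)

  wet <- stats::rbinom(n_days, 1L, regime$rain_prob)
  mean_depth <- regime$annual_rainfall / (365 * regime$rain_prob)
  rainfall <- wet * stats::rexp(n_days, rate = 1 / mean_depth)

  # humidity peaks in winter for the temperate preset (damper cold season)
  rh <- regime$mean_rh - regime$amp_rh * season +
    stats::rnorm(n_days, 0, regime$sd_rh)
  rh <- pmin(100, pmax(0, rh))

  out <- data.frame(
    date = dates, t_min = t_min, t_max = t_max,
    rainfall = rainfall, rel_humidity = rh
  )
  class(out) <- c("weather_series", class(out))
  validate_weather(out)
  out
}

# Seeded RNG scope: saves the caller's RNG state, seeds, and restores on
# exit so package functions never perturb user-level random streams.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}
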