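# Small in-code fixtures shared across test files.

# A tiny survey block: nr x nc houses, every house holding the same
# hand-specified containers (deterministic, no generator involved).
tiny_survey <- function(nr = 3, nc = 3,
                        types = c("large tanks", "cans"),
                        volumes = c(200, 0.5),
                        location = "outside",
                        fill = "manual") {
  n_houses <- nr * nc
  rows <- (seq_len(n_houses) - 1) %/% nc
  cols <- (seq_len(n_houses) - 1) %% nc
  per_house <- length(types)
  data.frame(
    container_id = sprintf("C%04d", seq_len(n_houses * per_house)),
    house_id = rep(sprintf("H%03d", seq_len(n_houses)), each = per_house),
    row = rep(rows, each = per_house),
    col = rep(cols, each = per_house),
    type = rep(types, n_houses),
    location = location,
    sun = 0,
    lid = 0L,
    fill = fill,
    volume_l = rep(volumes, n_houses)
  )
}

# Constant warm weather: daily mean air temperature = t_mean, no rain.
constant_weather <- function(n_days, t_mean = 27, spread = 5) {
  w <- data.frame(
    date = as.Date("2001-01-01") + seq_len(n_days) - 1,
    t_min = t_mean - spread,
    t_max = t_mean + spread,
    rainfall = 0,
    rel_humidity = 80
  )
  validate_weather(w)
  w
}

# Deterministic biology: all baseline survival = 1, so the only deaths
# are starvation-reserve exhaustion; useful for exact bookkeeping tests.
deterministic_params <- function(...) {
  biology_params(
    egg_daily_survival = 1, dry_egg_survival = 1,
    larva_daily_survival = 1, pupa_daily_survival = 1,
    adult_daily_survival = 1, dispersal_prob = 0,
    female_fraction = 1,
    ...
  )
}
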