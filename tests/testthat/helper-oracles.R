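# Independent reference implementations: deliberately naive O(N^2) loops
# and brute-force enumerations against which the vectorized statistics are
# checked.

oracle_moran <- function(x, rows, cols) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  w_sum <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- abs(rows[i] - rows[j]) + abs(cols[i] - cols[j])
      w <- 1 / d
      num <- num + w * (x[i] - xb) * (x[j] - xb)
      w_sum <- w_sum + w
    }
  }
  (n / w_sum) * num / sum((x - xb)^2)
}

oracle_l <- function(x, rows, cols, d_max) {
  n <- length(x)
  total <- 0
  s <- numeric(d_max)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- abs(rows[i] - rows[j]) + abs(cols[i] - cols[j])
      total <- total + x[i] * x[j]
      for (dd in seq_len(d_max)) {
        if (d <= dd) s[dd] <- s[dd] + x[i] * x[j]
      }
    }
  }
  sqrt(n * s / total / pi)
}

oracle_gi <- function(x, rows, cols, d) {
  n <- length(x)
  g <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nbsum <- 0
    w_i <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      dd <- abs(rows[i] - rows[j]) + abs(cols[i] - cols[j])
      if (dd <= d) {
        nbsum <- nbsum + x[j]
        w_i <- w_i + 1
      }
    }
    if (w_i == 0 || w_i == n - 1) next
    others <- x[-i]
    m <- mean(others)
    s <- stats::sd(others)
    if (s == 0) next
    g[i] <- (nbsum - w_i * m) / (s * sqrt(w_i * (n - 1 - w_i) / (n - 2)))
  }
  g
}

# Brute-force trailing-window positivity: for each day, loop containers
# and days in the window.
oracle_positivity <- function(ovi, window) {
  n_days <- nrow(ovi)
  n_cont <- ncol(ovi)
  frac <- numeric(n_days)
  for (t in seq_len(n_days)) {
    pos <- 0
    for (cc in seq_len(n_cont)) {
      hit <- FALSE
      for (s in max(1, t - window + 1):t) {
        if (ovi[s, cc]) hit <- TRUE
      }
      if (hit) pos <- pos + 1
    }
    frac[t] <- pos / n_cont
  }
  frac
}

# A random count map on an r x c lattice.
random_count_map <- function(r, c, lambda = 5) {
  pos <- expand.grid(row = 0:(r - 1), col = 0:(c - 1))
  count_map(pos$row, pos$col, stats::rpois(nrow(pos), lambda))
}
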