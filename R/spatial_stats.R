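# Spatial autocorrelation and cluster statistics on per-house counts:
# global Moran's I with inverse-distance weights, weighted second-order
# L functions with their increment contrast, and the local G statistic
# with cluster-membership labelling.

#' Construct a count map
#'
#' Per-house counts on grid positions, the common input of all spatial
#' statistics.
#'
#' @param row,col Integer grid coordinates (0-based or any consistent
#'   scheme), one per house/cell.
#' @param count Non-negative counts (e.g. pupae per house).
#' @return A data frame of class `count_map`.
#' @export
count_map <- function(row, col, count) {
  if (length(row) != length(col) || length(row) != length(count)) {
    stop("row, col and count must have equal length")
  }
  if (length(count) < 2L) stop("a count map needs at least 2 cells")
  if (any(count < 0)) stop("counts must be >= 0")
  if (anyDuplicated(paste(row, col))) stop("duplicate grid positions")
  out <- data.frame(row = row, col = col, count = as.numeric(count))
  class(out) <- c("count_map", class(out))
  out
}

#' Read a count map from CSV (`row,col,count`)
#' @param path File path.
#' @return A `count_map`.
#' @export
read_count_map <- function(path) {
  x <- utils::read.csv(path)
  count_map(x$row, x$col, x$count)
}

#' Inverse-distance spatial weights
#'
#' `w_ij = 1 / d(i, j)` with `d` the Manhattan grid distance, `w_ii = 0`.
#'
#' @param counts A `count_map` (positions are used, counts ignored).
#' @return A symmetric, zero-diagonal weight matrix.
#' @export
inverse_distance_weights <- function(counts) {
  d <- manhattan_dist_matrix(counts$row, counts$col)
  w <- ifelse(d > 0, 1 / d, 0)
  diag(w) <- 0
  w
}

#' Two-sided standard-normal critical value
#'
#' The |Z| threshold for a two-sided test at significance `alpha`; at
#' `alpha = 0.01` this is the 2.575 conventionally used to flag local-G
#' cluster members at the 0.01 confidence level.
#'
#' @param alpha Two-sided significance level.
#' @return The critical value `qnorm(1 - alpha / 2)`.
#' @export
critical_z <- function(alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stats::qnorm(1 - alpha / 2)
}

#' Moran's I with a permutation null
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`, with expectation `-1/(N-1)` under random spatial allocation.
#' The Z-score is computed from the permutation null: counts are shuffled
#' over cells with the weight matrix fixed.
#'
#' @param counts A `count_map`.
#' @param weights Weight matrix; defaults to inverse Manhattan distance.
#' @param n_perm Number of permutations for the null (0 skips the test).
#' @param seed Seed for the permutations.
#' @return A list of class `moran_result`: `I`, `expected` (= -1/(N-1)),
#'   `z`, `p_value`, `n_perm`, `perm_values`.
#' @export
morans_i <- function(counts, weights = NULL, n_perm = 999L, seed = 1L) {
  x <- counts$count
  n <- length(x)
  if (stats::var(x) == 0) {
    stop("Moran's I is undefined for constant counts (zero variance)")
  }
  if (is.null(weights)) weights <- inverse_distance_weights(counts)
  w_sum <- sum(weights)

  stat <- function(xx) {
    z <- xx - mean(xx)
    (n / w_sum) * as.numeric(z %*% weights %*% z) / sum(z^2)
  }
  i_obs <- stat(x)

  perm_values <- NULL
  z_score <- NA_real_
  p_value <- NA_real_
  if (n_perm > 0L) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
    perm_values <- vapply(seq_len(n_perm),
                          function(k) stat(sample(x)), numeric(1))
    z_score <- (i_obs - mean(perm_values)) / stats::sd(perm_values)
    p_value <- (1 + sum(abs(perm_values - mean(perm_values)) >=
                          abs(i_obs - mean(perm_values)))) / (n_perm + 1)
  }

  structure(list(
    I = i_obs,
    expected = -1 / (n - 1),
    z = z_score,
    p_value = p_value,
    n_perm = n_perm,
    perm_values = perm_values
  ), class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.5f (E[I] = %.5f), Z = %.3f, p = %.4f (%d permutations)\n",
              x$I, x$expected, x$z, x$p_value, x$n_perm))
  invisible(x)
}

# Cumulative within-distance pair sums S(d) = sum_i sum_{j in Omega_d(i)}
# x_i x_j for d = 1..d_max, plus the all-pairs total.
pair_sums <- function(x, dmat, d_max) {
  p <- outer(x, x)
  diag(p) <- 0
  total <- sum(p)
  s <- vapply(seq_len(d_max), function(d) sum(p[dmat <= d & dmat > 0]),
              numeric(1))
  list(s = s, total = total)
}

#' Weighted and unweighted L statistics with increment contrast
#'
#' Second-order (K-derived) statistics on lattice counts.  The weighted
#' form uses pair products of counts,
#' `K_w(d) = N * sum_i sum_{j in Omega_d(i)} x_i x_j / sum_i sum_{j != i}
#' x_i x_j`, `L_w(d) = sqrt(K_w(d) / pi)`; the unweighted `L(d)` applies
#' the same formula with every count replaced by 1, characterising the
#' house pattern itself.  The reported contrast is the increment
#' difference `delta(d) = (L_w(d) - L_w(d-1)) - (L(d) - L(d-1))` with
#' `L(0) = L_w(0) = 0`; positive values indicate counts more clustered
#' than the house pattern at that distance.  If counts are randomly
#' allocated over houses (in particular if they are constant), `L_w`
#' equals `L` and the contrast is identically zero.
#'
#' @param counts A `count_map` (not all zero).
#' @param d_max Largest Manhattan distance evaluated (>= 1).
#' @param n_perm Permutations for the null envelope of `delta` (0 = none).
#' @param envelope Two-sided envelope coverage (default 0.95).
#' @param seed Seed for the permutations.
#' @return A data frame of class `l_result` with columns `d`, `L_w`, `L`,
#'   `delta` and, with permutations, `lo`, `hi` (the envelope).
#' @export
l_statistics <- function(counts, d_max, n_perm = 0L, envelope = 0.95,
                         seed = 1L) {
  if (d_max < 1) stop("d_max must be >= 1")
  x <- counts$count
  if (all(x == 0)) stop("L statistics are undefined for all-zero counts")
  n <- length(x)
  dmat <- manhattan_dist_matrix(counts$row, counts$col)

  l_curve <- function(xx) {
    ps <- pair_sums(xx, dmat, d_max)
    k <- n * ps$s / ps$total
    sqrt(k / pi)
  }
  delta_of <- function(lw, l0) diff(c(0, lw)) - diff(c(0, l0))

  l0 <- l_curve(rep(1, n))
  lw <- l_curve(x)
  out <- data.frame(d = seq_len(d_max), L_w = lw, L = l0,
                    delta = delta_of(lw, l0))

  if (n_perm > 0L) {
    rng <- local_rng(seed)
    on.exit(rng$restore())
    perm_delta <- matrix(NA_real_, n_perm, d_max)
    for (k in seq_len(n_perm)) {
      perm_delta[k, ] <- delta_of(l_curve(sample(x)), l0)
    }
    a <- (1 - envelope) / 2
    out$lo <- apply(perm_delta, 2, stats::quantile, probs = a)
    out$hi <- apply(perm_delta, 2, stats::quantile, probs = 1 - a)
  }
  class(out) <- c("l_result", class(out))
  out
}

#' Local G statistic with cluster-membership labels
#'
#' For each house i, compares the sum of counts over the neighbourhood
#' `Omega_d(i)` (all houses within Manhattan distance `d`, excluding i
#' itself) with its expectation under random allocation, as a Z-like
#' score with expected value 0:
#' `G_i(d) = (sum_{j in Omega} x_j - W_i * m_i) / (s_i * sqrt(W_i *
#' (N - 1 - W_i) / (N - 2)))`, where `W_i = |Omega_d(i)|` and `m_i`,
#' `s_i` are the mean and standard deviation of the counts excluding
#' house i.  Houses with `|G_i| > z_threshold` are labelled members of a
#' positive (high-count) or negative (low-count) cluster; the default
#' threshold 2.575 corresponds to the 0.01 two-sided confidence level.
#'
#' @param counts A `count_map` with non-constant counts.
#' @param d Neighbourhood Manhattan distance (>= 1).
#' @param z_threshold |Z| labelling threshold (default 2.575).
#' @return A data frame of class `gi_result` with columns `row`, `col`,
#'   `g` (the score), `w_i` (neighbourhood size), `label`
#'   (`"positive-cluster"`, `"negative-cluster"`, `"none"`), and
#'   `degenerate` (TRUE where `W_i` is 0 or N-1 and the score is
#'   undefined).
#' @export
getis_gi <- function(counts, d, z_threshold = 2.575) {
  if (d < 1) stop("d must be >= 1")
  x <- counts$count
  n <- length(x)
  if (stats::var(x) == 0) {
    stop("local G is undefined for constant counts (zero variance)")
  }
  dmat <- manhattan_dist_matrix(counts$row, counts$col)
  nb <- dmat <= d & dmat > 0
  w_i <- rowSums(nb)
  nbsum <- as.vector(nb %*% x)

  tot <- sum(x)
  m_i <- (tot - x) / (n - 1)                      # mean excluding i
  ss <- sum(x^2)
  var_i <- (ss - x^2 - (n - 1) * m_i^2) / (n - 2) # sample var excluding i
  var_i <- pmax(var_i, 0)
  s_i <- sqrt(var_i)

  degenerate <- w_i == 0 | w_i == (n - 1) | s_i == 0
  denom <- s_i * sqrt(w_i * (n - 1 - w_i) / (n - 2))
  g <- ifelse(degenerate, NA_real_, (nbsum - w_i * m_i) / denom)

  label <- rep("none", n)
  label[!degenerate & g > z_threshold] <- "positive-cluster"
  label[!degenerate & g < -z_threshold] <- "negative-cluster"

  out <- data.frame(row = counts$row, col = counts$col, count = x,
                    g = g, w_i = w_i, label = label,
                    degenerate = degenerate)
  attr(out, "d") <- d
  attr(out, "z_threshold") <- z_threshold
  class(out) <- c("gi_result", class(out))
  out
}

#' Cluster-size profile over distances
#'
#' Counts how many houses are labelled positive- or negative-cluster
#' members at each neighbourhood distance, supporting summaries of the
#' largest distance at which any cluster is detected.
#'
#' @param counts A `count_map`.
#' @param d_list Distances to evaluate.
#' @param z_threshold |Z| labelling threshold.
#' @return A data frame with columns `d`, `n_positive`, `n_negative`,
#'   `n_members` (their sum).
#' @export
cluster_size_profile <- function(counts, d_list, z_threshold = 2.575) {
  constant <- stats::var(counts$count) == 0
  rows <- lapply(d_list, function(d) {
    if (constant) {
      # uniform counts: no house deviates, no cluster members anywhere
      return(data.frame(d = d, n_positive = 0L, n_negative = 0L))
    }
    gi <- getis_gi(counts, d, z_threshold)
    data.frame(
      d = d,
      n_positive = sum(gi$label == "positive-cluster"),
      n_negative = sum(gi$label == "negative-cluster")
    )
  })
  out <- do.call(rbind, rows)
  out$n_members <- out$n_positive + out$n_negative
  out
}

#' Write a set of spatial statistics to JSON
#'
#' @param counts A `count_map`.
#' @param path Output JSON path.
#' @param d_max Largest distance for the L and cluster profiles.
#' @param n_perm Permutations for Moran's I and the L envelope.
#' @param seed Seed.
#' @return `path`, invisibly.
#' @export
write_spatial_stats <- function(counts, path, d_max = 10L, n_perm = 999L,
                                seed = 1L) {
  mi <- morans_i(counts, n_perm = n_perm, seed = seed)
  ls <- l_statistics(counts, d_max = d_max, n_perm = n_perm, seed = seed)
  prof <- cluster_size_profile(counts, seq_len(d_max))
  out <- list(
    morans_i = list(I = mi$I, expected = mi$expected, z = mi$z,
                    p_value = mi$p_value, n_perm = mi$n_perm),
    l_increments = ls,
    cluster_profile = prof
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
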