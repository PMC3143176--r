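# Houses, containers, and the replicated simulation grid.

#' The fourteen container categories
#'
#' Canonical labels for the container types used throughout the package,
#' listed in the conventional decreasing order of pupal productivity.
#'
#' @return Character vector of length 14.
#' @export
container_types <- function() {
  c("plastic", "medium storage", "large tanks", "tires", "non-traditional",
    "cooking", "miscellaneous", "flower pots", "cans", "bath", "bottles",
    "natural", "wells", "pet")
}

fill_methods <- function() c("manual", "passive-rain", "assisted-rain")

#' Validate a container survey table
#'
#' A survey table has one row per container with columns `container_id`,
#' `house_id`, `row`, `col`, `type` (one of the 14 category labels),
#' `location` (`"inside"`/`"outside"`), `sun` (fraction 0-1), `lid`
#' (0/1), `fill` (`"manual"`, `"passive-rain"`, `"assisted-rain"`) and
#' `volume_l` (liters, > 0).
#'
#' @param x Survey data frame.
#' @return `x` invisibly.
#' @export
validate_survey <- function(x) {
  required <- c("container_id", "house_id", "row", "col", "type",
                "location", "sun", "lid", "fill", "volume_l")
  miss <- setdiff(required, names(x))
  if (length(miss) > 0L) {
    stop("survey table missing columns: ", paste(miss, collapse = ", "))
  }
  bad_type <- setdiff(unique(x$type), container_types())
  if (length(bad_type) > 0L) {
    stop("unknown container type(s): ", paste(bad_type, collapse = ", "))
  }
  if (!all(x$location %in% c("inside", "outside"))) {
    stop("container location must be 'inside' or 'outside'")
  }
  if (!all(x$fill %in% fill_methods())) {
    stop("fill method must be one of: ", paste(fill_methods(), collapse = ", "))
  }
  if (any(x$volume_l <= 0)) stop("container volumes must be > 0")
  if (any(x$sun < 0 | x$sun > 1)) stop("sun exposure must be in [0, 1]")
  if (anyDuplicated(x$container_id)) stop("duplicate container_id in survey")
  # every house occupies a single cell
  hp <- unique(x[, c("house_id", "row", "col")])
  if (anyDuplicated(hp$house_id)) {
    stop("a house_id is assigned to more than one grid cell")
  }
  invisible(x)
}

#' Read / write a container survey table
#'
#' Comma-delimited dialect with header
#' `container_id,house_id,row,col,type,location,sun,lid,fill,volume_l`.
#'
#' @param path File path.
#' @return For `read_survey`, a validated survey data frame.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_survey(x)
  x
}

#' @rdname read_survey
#' @param x Survey data frame.
#' @export
write_survey <- function(x, path) {
  validate_survey(x)
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build a replicated simulation grid from a survey subset
#'
#' Takes a rectangular block of surveyed houses (`block_rows` x
#' `block_cols`) and tiles `n_copies` independent copies of it into one
#' larger contiguous rectangle.  Within each copy the assignment of houses
#' to cells is an independent uniform permutation, so every house appears
#' exactly `n_copies` times in the grid but with different neighbours in
#' each copy.  Container inventories travel with their house untouched:
#' the same collection of containers is found in every copy of a given
#' house.
#'
#' Three grid-composition modes are expressible: the default replicated
#' mode (`n_copies > 1`), a single unreplicated block (`n_copies = 1`),
#' and a larger block simulated once (pass the larger survey with
#' matching `block_rows`/`block_cols` and `n_copies = 1`).
#'
#' @param survey Survey data frame (see [validate_survey()]) describing
#'   `block_rows * block_cols` houses.
#' @param block_rows,block_cols Dimensions of the surveyed block.
#' @param n_copies Number of copies to tile (>= 1).
#' @param seed Integer seed for the within-copy placement permutations.
#' @param layout `"compact"` tiles copies into the most nearly square
#'   rectangle (4 copies -> 2 x 2); `"strip"` lays copies side by side in
#'   one row.
#' @return A list of class `sim_grid` with elements `houses` (data frame:
#'   `cell`, `row`, `col`, `house_id`, `copy`), `containers` (survey rows
#'   replicated per copy, with `cell` and instance `uid`), and the grid
#'   dimensions.
#' @export
build_replicated_grid <- function(survey, block_rows, block_cols,
                                  n_copies = 1L, seed = 1L,
                                  layout = c("compact", "strip")) {
  layout <- match.arg(layout)
  validate_survey(survey)
  house_tab <- unique(survey[, c("house_id", "row", "col")])
  n_houses <- nrow(house_tab)
  if (n_houses != block_rows * block_cols) {
    stop("survey holds ", n_houses, " houses but block is ",
         block_rows, " x ", block_cols, " = ", block_rows * block_cols)
  }
  if (any(house_tab$row < 0 | house_tab$row >= block_rows) ||
      any(house_tab$col < 0 | house_tab$col >= block_cols)) {
    stop("house coordinates fall outside the stated block dimensions")
  }
  if (n_copies < 1L) stop("n_copies must be >= 1")

  if (layout == "compact") {
    tile_rows <- max(which(seq_len(floor(sqrt(n_copies))) |>
                             sapply(function(k) n_copies %% k == 0)))
    tile_cols <- n_copies %/% tile_rows
  } else {
    tile_rows <- 1L
    tile_cols <- n_copies
  }

  rng <- local_rng(seed)
  on.exit(rng$restore())

  cells_per_block <- block_rows * block_cols
  houses_list <- vector("list", n_copies)
  for (k in seq_len(n_copies)) {
    tr <- (k - 1L) %/% tile_cols   # tile position of this copy
    tc <- (k - 1L) %% tile_cols
    perm <- sample.int(n_houses)   # house -> cell within the block
    cell_in_block <- seq_len(cells_per_block)
    local_row <- (cell_in_block - 1L) %/% block_cols
    local_col <- (cell_in_block - 1L) %% block_cols
    houses_list[[k]] <- data.frame(
      row = tr * block_rows + local_row,
      col = tc * block_cols + local_col,
      house_id = house_tab$house_id[perm],
      copy = k
    )
  }
  houses <- do.call(rbind, houses_list)
  houses <- cbind(cell = seq_len(nrow(houses)), houses)

  cont_by_house <- split(survey, survey$house_id)
  cont_list <- vector("list", nrow(houses))
  for (i in seq_len(nrow(houses))) {
    cc <- cont_by_house[[as.character(houses$house_id[i])]]
    if (is.null(cc) || nrow(cc) == 0L) next
    cc$cell <- houses$cell[i]
    cc$copy <- houses$copy[i]
    cont_list[[i]] <- cc
  }
  containers <- do.call(rbind, cont_list)
  rownames(containers) <- NULL
  containers$uid <- seq_len(nrow(containers))
  containers$row <- NULL  # container coordinates live on the house/cell
  containers$col <- NULL

  structure(list(
    houses = houses,
    containers = containers,
    n_rows = tile_rows * block_rows,
    n_cols = tile_cols * block_cols,
    block_rows = block_rows,
    block_cols = block_cols,
    n_copies = n_copies,
    layout = layout,
    seed = seed
  ), class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat("Simulation grid:", x$n_rows, "x", x$n_cols, "cells;",
      nrow(x$houses), "houses (", x$n_copies, "copies of a",
      x$block_rows, "x", x$block_cols, "block );",
      nrow(x$containers), "containers\n")
  invisible(x)
}

#' Manhattan distance between grid locations
#'
#' The model's distance metric: number of horizontal/vertical grid steps
#' separating two cells, `|row_a - row_b| + |col_a - col_b|`.
#'
#' @param row_a,col_a,row_b,col_b Grid coordinates (vectorized).
#' @return Integer distance(s).
#' @export
manhattan_distance <- function(row_a, col_a, row_b, col_b) {
  abs(row_a - row_b) + abs(col_a - col_b)
}

# Full pairwise Manhattan distance matrix for a set of cells.
manhattan_dist_matrix <- function(rows, cols) {
  abs(outer(rows, rows, "-")) + abs(outer(cols, cols, "-"))
}
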