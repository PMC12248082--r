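#' Nearest-neighbor regularity index
#'
#' The classic mosaic regularity statistic: mean of the nearest-neighbor
#' distances divided by their standard deviation (n - 1 denominator). A
#' Poisson (fully random) pattern scores about 1.91; regular mosaics score
#' higher because exclusion zones shrink the nearest-neighbor spread.
#'
#' @param pattern a [pointpattern] with at least 3 points.
#' @return dimensionless index; `Inf` (with a warning) when all
#'   nearest-neighbor distances are identical.
#' @export
nn_regularity_index <- function(pattern) {
  pts <- pattern$points
  n <- nrow(pts)
  if (n < 3) stop("regularity index needs >= 3 points")
  nn <- nn_distances(pts$x, pts$y)
  s <- stats::sd(nn)
  if (s == 0) {
    warning("degenerate pattern: all nearest-neighbor distances identical")
    return(Inf)
  }
  mean(nn) / s
}

# nearest-neighbor distance of every point (O(n^2), fine at mosaic sizes)
nn_distances <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Regularity index ratio against matched random patterns
#'
#' Normalizes the nearest-neighbor regularity index by the median index of
#' `n_random` completely random (CSR) patterns with the same point count and
#' window — the ratio is about 1 for random input and exceeds 1 for mosaics
#' with exclusion zones.
#'
#' @param pattern a [pointpattern].
#' @param n_random number of CSR reference patterns (default 99).
#' @param seed integer seed for the CSR references.
#' @return dimensionless ratio.
#' @export
regularity_index_ratio <- function(pattern, n_random = 99, seed = NULL) {
  ri <- nn_regularity_index(pattern)
  n <- nrow(pattern$points)
  win <- pattern$window
  width <- win[3] - win[1]
  height <- win[4] - win[2]
  ref <- with_seed_opt(seed, {
    vapply(seq_len(n_random), function(i) {
      p <- pointpattern(
        data.frame(x = stats::runif(n, win[1], win[3]),
                   y = stats::runif(n, win[2], win[4])),
        win)
      nn_regularity_index(p)
    }, numeric(1))
  })
  ri / stats::median(ref)
}

#' Density recovery profile (spatial autocorrelogram)
#'
#' Annular density of neighbors versus distance from each cell, after
#' Rodieck: for every point at least `max_radius` from each window edge (the
#' border-corrected reference set), neighbor distances are binned into
#' annuli of width `bin_width`, and each annulus count is divided by the
#' number of reference points times the annulus area. The central dip of a
#' mosaic recovers to the mean density; its deficit, converted to the radius
#' of an equivalent hard step, is the effective exclusion radius:
#' `sqrt(deficit / (pi * mean_density))`, accumulating the deficit from
#' distance zero up to the first annulus at or above the mean density.
#'
#' @param pattern a [pointpattern].
#' @param bin_width annulus width in micrometers.
#' @param max_radius largest distance profiled; at most half the shorter
#'   window side.
#' @param n_random optional count of CSR reference patterns for the
#'   regularity-index ratio reported alongside (skipped when `NULL`).
#' @param seed seed for the CSR references.
#' @return a `drp_result`: list with `bin_edges`, `annulus_density`,
#'   `annulus_count`, `n_reference`, `mean_density`, `effective_radius`,
#'   `regularity_index`, and `regularity_index_ratio` (NA unless `n_random`
#'   is given).
#' @export
density_recovery_profile <- function(pattern, bin_width, max_radius,
                                     n_random = NULL, seed = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  win <- pattern$window
  short_side <- min(win[3] - win[1], win[4] - win[2])
  if (max_radius > short_side / 2) {
    stop("max_radius must be <= half the shorter window side")
  }
  pts <- pattern$points
  n <- nrow(pts)
  area <- (win[3] - win[1]) * (win[4] - win[2])
  mean_density <- n / area
  interior <- pts$x >= win[1] + max_radius & pts$x <= win[3] - max_radius &
    pts$y >= win[2] + max_radius & pts$y <= win[4] - max_radius
  n_ref <- sum(interior)
  if (n_ref == 0) {
    stop("no reference points at least max_radius from every edge; ",
         "use a larger window or a smaller max_radius")
  }
  edges <- seq(0, max_radius, by = bin_width)
  if (edges[length(edges)] < max_radius) edges <- c(edges, max_radius)
  n_bins <- length(edges) - 1
  counts <- integer(n_bins)
  ref_idx <- which(interior)
  for (i in ref_idx) {
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
    d <- d[-i]
    d <- d[d < max_radius]
    if (length(d) > 0) {
      counts <- counts + tabulate(findInterval(d, edges, left.open = TRUE,
                                               rightmost.closed = FALSE),
                                  nbins = n_bins)
    }
  }
  ann_area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  density <- counts / (n_ref * ann_area)
  # dead-space deficit: accumulate up to the first annulus that recovers
  deficit <- 0
  for (b in seq_len(n_bins)) {
    if (density[b] >= mean_density) break
    deficit <- deficit + (mean_density - density[b]) * ann_area[b]
  }
  effective_radius <- sqrt(deficit / (pi * mean_density))
  rir <- if (!is.null(n_random)) {
    regularity_index_ratio(pattern, n_random = n_random, seed = seed)
  } else NA_real_
  structure(list(bin_edges = edges, annulus_density = density,
                 annulus_count = counts, n_reference = n_ref,
                 mean_density = mean_density,
                 effective_radius = effective_radius,
                 regularity_index = nn_regularity_index(pattern),
                 regularity_index_ratio = rir),
            class = "drp_result")
}

#' Read a point pattern from CSV
#'
#' Expects columns `x_um`, `y_um` (or `x`, `y`).
#'
#' @param path CSV file path.
#' @param window observation window `(x_min, y_min, x_max, y_max)`; defaults
#'   to the bounding box of the points.
#' @return a [pointpattern].
#' @export
read_points_csv <- function(path, window = NULL) {
  df <- utils::read.csv(path)
  names(df) <- sub("_um$", "", names(df))
  if (is.null(window)) {
    window <- c(min(df$x), min(df$y), max(df$x), max(df$y))
  }
  pointpattern(df[, c("x", "y")], window)
}

#' Write a point pattern to CSV
#'
#' @param pattern a [pointpattern].
#' @param path output CSV path; columns `x_um`, `y_um`.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(pattern, path) {
  utils::write.csv(
    stats::setNames(pattern$points, c("x_um", "y_um")), path, row.names = FALSE)
  invisible(path)
}
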