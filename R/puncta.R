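#' Filter puncta by volume-equivalent diameter
#'
#' Drops puncta whose volume-equivalent sphere diameter `d = (6V / pi)^(1/3)`
#' is strictly smaller than `min_diameter`; a punctum exactly at the
#' threshold is retained. The default 0.5 um removes segmentation noise
#' below the optical resolution of a confocal punctum.
#'
#' @param puncta a `puncta_set` (see [puncta_set()]).
#' @param min_diameter micrometers (default 0.5).
#' @return a `puncta_set` with the retained puncta (possibly empty).
#' @export
filter_puncta <- function(puncta, min_diameter = 0.5) {
  d <- (6 * puncta$puncta$volume / pi)^(1 / 3)
  keep <- d >= min_diameter
  out <- puncta
  out$puncta <- puncta$puncta[keep, , drop = FALSE]
  out
}

#' Per-punctum counts, volumes and soma distances
#'
#' Number of puncta, their volumes, Euclidean distances from the soma
#' center, and distances normalized by the parent arbor's radial extent
#' (clipped to \[0, 1.05\]; clip events are reported in the result).
#'
#' @param puncta a `puncta_set`.
#' @return list with `count`, `volumes`, `mean_volume`, `distances`,
#'   `mean_distance`, `normalized_distances`, `n_clipped`. An empty set
#'   yields `count = 0` with the summaries absent (`NA`), not an error.
#' @export
puncta_stats <- function(puncta) {
  if (puncta$arbor_radial_extent <= 0) stop("arbor_radial_extent must be > 0")
  p <- puncta$puncta
  if (nrow(p) == 0) {
    return(list(count = 0L, volumes = numeric(0), mean_volume = NA_real_,
                distances = numeric(0), mean_distance = NA_real_,
                normalized_distances = numeric(0), n_clipped = 0L))
  }
  ctr <- puncta$soma_center
  d <- sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2 + (p$z - ctr[3])^2)
  nd <- d / puncta$arbor_radial_extent
  n_clipped <- sum(nd > 1.05)
  nd <- pmin(nd, 1.05)
  list(count = nrow(p), volumes = p$volume, mean_volume = mean(p$volume),
       distances = d, mean_distance = mean(d),
       normalized_distances = nd, n_clipped = n_clipped)
}

#' Fraction of puncta in the distal arbor compartment
#'
#' Fraction of puncta whose normalized soma distance exceeds `boundary`; the
#' default 2/3 measures confinement of presynaptic outputs to the outer
#' third of the dendritic arbor.
#'
#' @param puncta a non-empty `puncta_set`.
#' @param boundary normalized-distance boundary (default 2/3).
#' @return fraction in \[0, 1\].
#' @export
compartmentalization_fraction <- function(puncta, boundary = 2 / 3) {
  stats <- puncta_stats(puncta)
  if (stats$count == 0) stop("compartmentalization undefined for an empty puncta set")
  mean(stats$normalized_distances > boundary)
}

#' Read a puncta set from CSV
#'
#' Expects columns `x_um`, `y_um`, `z_um`, `volume_um3` (or unsuffixed
#' `x`, `y`, `z`, `volume`).
#'
#' @param path CSV file path.
#' @param soma_center numeric xyz of the parent soma.
#' @param arbor_radial_extent parent arbor radial extent, micrometers.
#' @return a `puncta_set`.
#' @export
read_puncta_csv <- function(path, soma_center, arbor_radial_extent) {
  df <- utils::read.csv(path)
  names(df) <- sub("_um3?$", "", names(df))
  puncta_set(df[, c("x", "y", "z", "volume")], soma_center, arbor_radial_extent)
}

#' Write a puncta set to CSV
#'
#' @param puncta a `puncta_set`.
#' @param path output CSV path; columns `x_um`, `y_um`, `z_um`, `volume_um3`.
#' @return `path`, invisibly.
#' @export
write_puncta_csv <- function(puncta, path) {
  utils::write.csv(
    stats::setNames(puncta$puncta, c("x_um", "y_um", "z_um", "volume_um3")),
    path, row.names = FALSE)
  invisible(path)
}
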