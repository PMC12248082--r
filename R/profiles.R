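#' Bin an IPL lamination profile into 20 depth sections
#'
#' Divides the inner plexiform layer into 20 equal depth sections and
#' reports the fraction of total fluorescence in each, normalizing away
#' variation in absolute IPL thickness and staining intensity. Section `k`
#' collects samples with depth in `((k - 1) / 20, k / 20]`; depth 0 goes to
#' section 1.
#'
#' @param profile a [lamination_profile], or a list with `depth` and
#'   `intensity`.
#' @return numeric length 20 summing to 1.
#' @export
bin_lamination <- function(profile) {
  depth <- profile$depth
  intensity <- profile$intensity
  total <- sum(intensity)
  if (total <= 0) stop("degenerate lamination profile: total intensity is 0")
  bin <- pmax(ceiling(depth * 20), 1)
  bin <- pmin(bin, 20)
  out <- vapply(1:20, function(k) sum(intensity[bin == k]), numeric(1))
  out / total
}

#' Background-normalized ROI fluorescence intensity
#'
#' Per-cell mean ROI intensity divided by the mean intensity of the inverse
#' (background) ROI — the normalized fluorescence signal used for comparing
#' staining levels across images.
#'
#' @param cell_means numeric, mean intensity of each cell ROI (>= 0).
#' @param background_mean mean intensity of the background ROI (> 0).
#' @return per-cell normalized ratios.
#' @export
normalized_intensity <- function(cell_means, background_mean) {
  if (any(cell_means < 0)) stop("cell means must be >= 0")
  if (length(background_mean) != 1 || background_mean <= 0) {
    stop("background_mean must be a single value > 0")
  }
  cell_means / background_mean
}

#' Band-concentration summary of a binned lamination profile
#'
#' Scalar statistic for group comparison of 20-bin profiles: the fraction of
#' total intensity within one bin of each of the two highest profile peaks —
#' high for cleanly bilaminated arbors, low for diffuse stratification.
#'
#' @param binned_20 numeric length 20 from [bin_lamination()].
#' @return fraction in \[0, 1\].
#' @export
band_concentration <- function(binned_20) {
  if (length(binned_20) != 20) stop("expected 20 bins")
  ord <- order(binned_20, decreasing = TRUE)
  p1 <- ord[1]
  # second peak: highest bin not adjacent to the first
  p2 <- ord[which(abs(ord - p1) > 1)[1]]
  sel <- unique(pmax(pmin(c(p1 - 1, p1, p1 + 1, p2 - 1, p2, p2 + 1), 20), 1))
  sum(binned_20[sel])
}

#' Read a lamination profile from CSV
#'
#' Expects columns `depth` (normalized, \[0, 1\]) and `intensity`.
#'
#' @param path CSV file path.
#' @return a [lamination_profile].
#' @export
read_lamination_csv <- function(path) {
  df <- utils::read.csv(path)
  ord <- order(df$depth)
  lamination_profile(df$depth[ord], df$intensity[ord])
}
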