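#' Construct a planar point pattern
#'
#' Soma centers in a rectangular observation window; the unit of mosaic
#' spacing analysis.
#'
#' @param points data.frame or matrix with columns `x`, `y` (micrometers).
#' @param window numeric length 4: `(x_min, y_min, x_max, y_max)`.
#' @return a `pointpattern`.
#' @export
pointpattern <- function(points, window) {
  points <- as.data.frame(points)
  if (nrow(points) > 0) {
    names(points)[1:2] <- c("x", "y")
    if (any(points$x < window[1] | points$x > window[3] |
            points$y < window[2] | points$y > window[4])) {
      stop("points fall outside the window")
    }
  } else {
    points <- data.frame(x = numeric(0), y = numeric(0))
  }
  if (window[3] <= window[1] || window[4] <= window[2]) {
    stop("window must have positive area")
  }
  structure(list(points = points, window = as.numeric(window)),
            class = "pointpattern")
}

#' @export
print.pointpattern <- function(x, ...) {
  cat(sprintf("<pointpattern> %d points in [%g, %g] x [%g, %g] um\n",
              nrow(x$points), x$window[1], x$window[3], x$window[2], x$window[4]))
  invisible(x)
}

#' Generate a soma mosaic (hard-core or fully random point pattern)
#'
#' Places `n_points` soma centers in a rectangular window with every pair of
#' points at least `dmin` apart (a hard-core exclusion zone, the classic
#' minimal model of a retinal mosaic); `dmin = 0` gives complete spatial
#' randomness (CSR). Sparse packings come from dart throwing (random
#' sequential placement). Dart throwing jams near 55% disc coverage, so
#' denser requests fall back to a perturbed triangular lattice randomized by
#' hard-core Metropolis moves; if even the lattice cannot hold `n_points`
#' the generator fails with an error naming `dmin` and `n_points`.
#'
#' @param n_points number of somas (>= 0).
#' @param window length-2 numeric, window width and height in micrometers.
#' @param dmin hard-core exclusion radius in micrometers (0 = CSR).
#' @param seed integer seed.
#' @param max_attempts dart-throwing budget before giving up.
#' @return a [pointpattern] with window `(0, 0, width, height)`.
#' @examples
#' m <- gen_mosaic(100, c(300, 300), dmin = 30, seed = 1)
#' nn_regularity_index(m)
#' @export
gen_mosaic <- function(n_points, window = c(300, 300), dmin = 0, seed = NULL,
                       max_attempts = 200 * n_points + 1000) {
  if (n_points < 0) stop("n_points must be >= 0")
  if (any(window <= 0)) stop("window dimensions must be > 0")
  if (dmin < 0) stop("dmin must be >= 0")
  win <- c(0, 0, window[1], window[2])
  if (n_points == 0) {
    return(pointpattern(data.frame(x = numeric(0), y = numeric(0)), win))
  }
  with_seed_opt(seed, {
    if (dmin == 0) {
      pts <- data.frame(x = stats::runif(n_points, 0, window[1]),
                        y = stats::runif(n_points, 0, window[2]))
      return(pointpattern(pts, win))
    }
    xs <- numeric(n_points); ys <- numeric(n_points)
    placed <- 0L
    for (attempt in seq_len(max_attempts)) {
      px <- stats::runif(1, 0, window[1])
      py <- stats::runif(1, 0, window[2])
      if (placed == 0L ||
          min((xs[seq_len(placed)] - px)^2 + (ys[seq_len(placed)] - py)^2) >= dmin^2) {
        placed <- placed + 1L
        xs[placed] <- px; ys[placed] <- py
        if (placed == n_points) break
      }
    }
    if (placed < n_points) {
      # beyond the dart-throwing (RSA) jamming density: seed from a
      # triangular lattice at pitch just above dmin, then randomize with
      # hard-core Metropolis moves (uniform relocation proposals accepted
      # when they respect dmin)
      s <- dmin * 1.005
      ys_lat <- seq(0, window[2], by = s * sqrt(3) / 2)
      lat <- do.call(rbind, lapply(seq_along(ys_lat), function(j) {
        off <- ((j - 1) %% 2) * s / 2
        xs_lat <- seq(off, window[1], by = s)
        cbind(xs_lat, rep(ys_lat[j], length(xs_lat)))
      }))
      if (nrow(lat) < n_points) {
        stop("mosaic generation failed: could not place ", n_points,
             " points at dmin = ", dmin, " um in a ", window[1], " x ",
             window[2], " window")
      }
      keep <- sample.int(nrow(lat), n_points)
      xs <- lat[keep, 1]; ys <- lat[keep, 2]
      for (move in seq_len(30L * n_points)) {
        i <- sample.int(n_points, 1)
        px <- stats::runif(1, 0, window[1])
        py <- stats::runif(1, 0, window[2])
        d2 <- (xs[-i] - px)^2 + (ys[-i] - py)^2
        if (min(d2) >= dmin^2) {
          xs[i] <- px; ys[i] <- py
        }
      }
    }
    pointpattern(data.frame(x = xs, y = ys), win)
  })
}

#' Generate synthetic directional spike responses
#'
#' Emulates sorted multielectrode-array units responding to a stimulus moving
#' in `n_directions` evenly spaced directions, `n_epochs` repeats each.
#' Direction-selective (DS) units fire Poisson spike counts with per-epoch
#' mean `epoch_dur * (baseline_rate + ds_amplitude * exp(kappa *
#' (cos(theta - mu) - 1)))` — a von Mises tuning profile with preferred
#' direction `mu` drawn uniformly from the direction set. Non-DS units are
#' Poisson at the baseline rate in every direction. Ground-truth labels and
#' preferred directions are kept alongside the counts for recovery studies.
#'
#' @param n_units number of units.
#' @param frac_ds fraction of units that are direction selective, in \[0, 1\];
#'   the DS count is `round(frac_ds * n_units)`, assigned to random units.
#' @param baseline_rate baseline firing rate, spikes/s (>= 0).
#' @param ds_amplitude rate above baseline at the preferred direction,
#'   spikes/s (>= 0).
#' @param kappa von Mises concentration (>= 0; 0 removes tuning).
#' @param n_directions even direction count (default 12, i.e. 30 deg steps).
#' @param n_epochs stimulus repeats per direction.
#' @param epoch_dur epoch duration in seconds.
#' @param seed integer seed.
#' @return a `directional_responses`: list with `directions_deg`,
#'   `epoch_dur_s`, `units` (each `unit_id` + `counts` epoch x direction
#'   matrix), and simulation truth `is_ds`, `mu_true_deg`.
#' @export
gen_mea_responses <- function(n_units, frac_ds = 0.3, baseline_rate = 2,
                              ds_amplitude = 20, kappa = 4, n_directions = 12,
                              n_epochs = 5, epoch_dur = 3, seed = NULL) {
  if (n_units < 1) stop("n_units must be >= 1")
  if (frac_ds < 0 || frac_ds > 1) stop("frac_ds must be in [0, 1]")
  if (baseline_rate < 0 || ds_amplitude < 0) stop("rates must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (n_directions < 2 || n_directions %% 2 != 0) {
    stop("n_directions must be even and >= 2 so an exact opposite direction exists")
  }
  if (n_epochs < 1 || epoch_dur <= 0) stop("n_epochs >= 1 and epoch_dur > 0 required")
  directions <- seq(0, 360 - 360 / n_directions, by = 360 / n_directions)
  with_seed_opt(seed, {
    n_ds <- round(frac_ds * n_units)
    is_ds <- rep(FALSE, n_units)
    if (n_ds > 0) is_ds[sample.int(n_units, n_ds)] <- TRUE
    mu_true <- rep(NA_real_, n_units)
    theta <- directions * pi / 180
    units <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      if (is_ds[i]) {
        mu_true[i] <- sample(directions, 1)
        rate <- baseline_rate +
          ds_amplitude * exp(kappa * (cos(theta - mu_true[i] * pi / 180) - 1))
      } else {
        rate <- rep(baseline_rate, n_directions)
      }
      lam <- epoch_dur * rate
      counts <- matrix(stats::rpois(n_epochs * n_directions,
                                    rep(lam, each = n_epochs)),
                       nrow = n_epochs, ncol = n_directions)
      units[[i]] <- list(unit_id = i, counts = counts)
    }
    structure(list(directions_deg = directions, epoch_dur_s = epoch_dur,
                   units = units, is_ds = is_ds, mu_true_deg = mu_true),
              class = "directional_responses")
  })
}

#' Build a square multielectrode-array layout
#'
#' Centers of a square electrode grid: `k` rows at center-to-center spacing
#' `pitch`, where `k` is the largest count whose footprint
#' `(k - 1) * pitch + electrode_side` fits within `span`. Printed array
#' dimensions are typically rounded (e.g. a 64 x 60 um grid of 21 um
#' electrodes is 3801 um, quoted as 3.8 mm), so the fit allows a small
#' relative tolerance on `span`.
#'
#' @param pitch center-to-center spacing, micrometers (> 0).
#' @param electrode_side electrode edge length, micrometers.
#' @param span side of the square array area, micrometers (>= electrode_side).
#' @param span_tol absolute slack added to `span` when counting rows;
#'   default 0.5% of `span`, accommodating spans quoted at limited precision.
#' @return list with `centers` (data.frame x, y of electrode centers),
#'   `n_rows` and `n_electrodes`.
#' @examples
#' gen_mea_layout(pitch = 60, electrode_side = 21, span = 3800)$n_electrodes
#' @export
gen_mea_layout <- function(pitch, electrode_side, span,
                           span_tol = 0.005 * span) {
  if (pitch <= 0) stop("pitch must be > 0")
  if (span < electrode_side) stop("span must be >= electrode_side")
  k <- floor((span + span_tol - electrode_side) / pitch) + 1
  k <- max(1L, as.integer(k))
  offs <- electrode_side / 2 + pitch * (seq_len(k) - 1)
  centers <- expand.grid(x = offs, y = offs)
  list(centers = centers, n_rows = k, n_electrodes = k^2)
}

#' Construct a lamination profile
#'
#' Fluorescence intensity versus normalized inner-plexiform-layer depth;
#' depth 0 and 1 are the two IPL borders.
#'
#' @param depth numeric in \[0, 1\], ascending.
#' @param intensity non-negative intensities, same length.
#' @return a `lamination_profile`.
#' @export
lamination_profile <- function(depth, intensity) {
  if (length(depth) != length(intensity)) stop("depth and intensity lengths differ")
  if (any(depth < 0 | depth > 1)) stop("depths must lie in [0, 1]")
  if (is.unsorted(depth)) stop("depths must be ascending")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  structure(list(depth = depth, intensity = intensity),
            class = "lamination_profile")
}

#' Generate a synthetic IPL lamination profile
#'
#' Intensity versus normalized depth as a sum of Gaussian bands plus
#' truncated-at-zero Gaussian noise, sampled at `n_samples` uniform depths.
#' The defaults emulate the two starburst dendrite bands (sublaminae S2 and
#' S4); band positions are placeholders, tunable per dataset.
#'
#' @param band_centers normalized depths of the bands, each in \[0, 1\].
#' @param band_sd band width (Gaussian SD) in normalized depth.
#' @param weights non-negative band weights, one per center.
#' @param noise_sd SD of additive noise (intensity units); the noisy signal
#'   is clipped at zero.
#' @param n_samples number of uniformly spaced depth samples.
#' @param seed integer seed.
#' @return a [lamination_profile].
#' @export
gen_lamination <- function(band_centers = c(0.3, 0.7), band_sd = 0.05,
                           weights = rep(1, length(band_centers)),
                           noise_sd = 0, n_samples = 200, seed = NULL) {
  if (length(band_centers) != length(weights)) {
    stop("band_centers and weights lengths differ")
  }
  if (any(band_centers < 0 | band_centers > 1)) stop("band centers must lie in [0, 1]")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (band_sd <= 0 && length(band_centers) > 0) stop("band_sd must be > 0")
  depth <- seq(0, 1, length.out = n_samples)
  signal <- rep(0, n_samples)
  for (i in seq_along(band_centers)) {
    signal <- signal + weights[i] * stats::dnorm(depth, band_centers[i], band_sd)
  }
  if ((length(band_centers) == 0 || all(weights == 0)) && noise_sd == 0) {
    warning("degenerate lamination profile: no bands and no noise; all-zero profile")
  }
  with_seed_opt(seed, {
    if (noise_sd > 0) {
      signal <- pmax(signal + stats::rnorm(n_samples, 0, noise_sd), 0)
    }
    lamination_profile(depth, signal)
  })
}

#' Construct a puncta set
#'
#' Synaptic puncta (centers and volumes) tied to a parent arbor's soma
#' position and radial extent.
#'
#' @param puncta data.frame with columns `x`, `y`, `z` (micrometers) and
#'   `volume` (cubic micrometers, > 0).
#' @param soma_center numeric xyz of the parent soma.
#' @param arbor_radial_extent radial extent of the parent arbor (> 0).
#' @return a `puncta_set`.
#' @export
puncta_set <- function(puncta, soma_center, arbor_radial_extent) {
  puncta <- as.data.frame(puncta)
  required <- c("x", "y", "z", "volume")
  if (!all(required %in% names(puncta))) {
    stop("puncta needs columns x, y, z, volume")
  }
  if (any(puncta$volume <= 0)) stop("puncta volumes must be > 0")
  if (arbor_radial_extent <= 0) stop("arbor_radial_extent must be > 0")
  structure(list(puncta = puncta[, required],
                 soma_center = as.numeric(soma_center)[1:3],
                 arbor_radial_extent = arbor_radial_extent),
            class = "puncta_set")
}
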