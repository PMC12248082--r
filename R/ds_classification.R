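#' Filter units by total spike count
#'
#' Units whose summed spike count over all epochs and directions falls below
#' `min_total` are dropped before any tuning analysis; the default 400
#' removes units too sparse to classify.
#'
#' @param responses a `directional_responses` (see [gen_mea_responses()] or
#'   [read_responses_json()]).
#' @param min_total inclusive minimum total spike count (default 400).
#' @return integer vector of retained unit ids.
#' @export
filter_min_spikes <- function(responses, min_total = 400) {
  totals <- vapply(responses$units, function(u) sum(u$counts), numeric(1))
  ids <- vapply(responses$units, function(u) as.integer(u$unit_id), integer(1))
  ids[totals >= min_total]
}

#' Direction selectivity index
#'
#' DSI = (P - N) / (P + N), with P the mean spike count in the preferred
#' direction (the direction with maximal mean count; ties break toward the
#' smaller angle) and N the mean count in the opposite (null) direction. 0
#' is untuned, 1 perfectly selective.
#'
#' @param mean_counts per-direction mean spike counts.
#' @param directions_deg direction angles in degrees, evenly spaced, even
#'   count.
#' @return list with `dsi`, `preferred_deg`, `null_deg`.
#' @export
compute_dsi <- function(mean_counts, directions_deg) {
  n_dir <- length(directions_deg)
  if (n_dir %% 2 != 0) stop("direction count must be even")
  if (length(mean_counts) != n_dir) stop("mean_counts/directions length mismatch")
  if (all(mean_counts == 0)) stop("undefined DSI: all mean counts are zero")
  pref_idx <- which(mean_counts == max(mean_counts))
  pref_idx <- pref_idx[which.min(directions_deg[pref_idx])]
  pref <- directions_deg[pref_idx]
  null_dir <- (pref + 180) %% 360
  null_idx <- which(directions_deg %% 360 == null_dir)
  p <- mean_counts[pref_idx]
  n <- mean_counts[null_idx]
  list(dsi = (p - n) / (p + n), preferred_deg = pref, null_deg = null_dir)
}

# von Mises-style tuning curve over angles in degrees
von_mises_curve <- function(theta_deg, baseline, amplitude, kappa, mu_deg) {
  baseline + amplitude * exp(kappa * (cos((theta_deg - mu_deg) * pi / 180) - 1))
}

#' Fit a von Mises tuning curve to per-direction mean counts
#'
#' Least-squares fit of `r(theta) = baseline + amplitude * exp(kappa *
#' (cos(theta - mu) - 1))`, with multi-start optimization seeding `mu` at
#' every observed direction (deterministic start order, best sum of squares
#' wins). Fit quality is the coefficient of determination R-squared = 1 -
#' SS_res / SS_tot about the mean of the per-direction means; a flat cell
#' (zero variance across directions) gets quality 0 and kappa 0 by
#' convention rather than an error.
#'
#' @param mean_counts per-direction mean spike counts.
#' @param directions_deg direction angles in degrees (>= 4 directions).
#' @return a `tuning_fit`: list with `mu_deg` (in \[0, 360)), `kappa`,
#'   `amplitude`, `baseline`, `fit_quality`.
#' @export
fit_von_mises <- function(mean_counts, directions_deg) {
  if (length(directions_deg) < 4) stop("need >= 4 directions for a tuning fit")
  if (length(mean_counts) != length(directions_deg)) {
    stop("mean_counts/directions length mismatch")
  }
  ss_tot <- sum((mean_counts - mean(mean_counts))^2)
  if (ss_tot == 0) {
    return(structure(list(mu_deg = directions_deg[1], kappa = 0,
                          amplitude = 0, baseline = mean_counts[1],
                          fit_quality = 0), class = "tuning_fit"))
  }
  # amplitude and kappa fitted on the log scale, keeping both positive
  obj <- function(par) {
    pred <- von_mises_curve(directions_deg, par[1], exp(par[2]), exp(par[3]), par[4])
    sum((pred - mean_counts)^2)
  }
  amp0 <- max(mean_counts) - min(mean_counts)
  base0 <- min(mean_counts)
  best <- NULL
  for (mu0 in directions_deg) {
    for (kappa0 in c(1, 4)) {
      fit <- stats::optim(c(base0, log(amp0), log(kappa0), mu0), obj,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  par <- best$par
  baseline <- par[1]
  amplitude <- exp(par[2])
  kappa <- exp(par[3])
  mu <- par[4] %% 360
  pred <- von_mises_curve(directions_deg, baseline, amplitude, kappa, mu)
  quality <- 1 - sum((pred - mean_counts)^2) / ss_tot
  structure(list(mu_deg = mu, kappa = kappa, amplitude = amplitude,
                 baseline = baseline, fit_quality = quality),
            class = "tuning_fit")
}

#' Tuning width (full width at half maximum) of a von Mises fit
#'
#' Width of the fitted tuning curve above baseline at half its peak
#' amplitude. The half-maximum offset solves `exp(kappa * (cos(d) - 1)) =
#' 1/2`, giving `FWHM = 2 * acos(1 - log(2) / kappa)` in degrees for
#' `kappa >= log(2) / 2`; flatter curves never fall to half amplitude and
#' report 360 degrees.
#'
#' @param fit a `tuning_fit` from [fit_von_mises()], or any list with
#'   `amplitude` and `kappa`.
#' @return width in degrees.
#' @export
tuning_width_fwhm <- function(fit) {
  if (fit$amplitude <= 0 || fit$kappa <= 0) {
    stop("tuning width undefined: amplitude and kappa must be > 0")
  }
  arg <- 1 - log(2) / fit$kappa
  if (arg < -1) return(360)
  2 * acos(arg) * 180 / pi
}

#' Classify direction-selective ganglion cells
#'
#' The full classification pipeline for sorted units: drop units under
#' `min_total` total spikes, compute per-direction mean counts, DSI, the von
#' Mises tuning fit and FWHM, mean spikes per epoch and in the preferred
#' direction, and call a unit a putative DSGC when DSI exceeds `dsi_threshold`
#' and fit quality exceeds `fit_threshold` (both strict) and the unit fires
#' at least `min_pref_spikes` spikes on average in its preferred direction.
#' A unit that fails any step is recorded as non-DS with a reason code; the
#' batch never aborts.
#'
#' @param responses a `directional_responses`.
#' @param min_total inclusive minimum total spikes (default 400).
#' @param dsi_threshold strict DSI threshold (default 0.37).
#' @param fit_threshold strict fit-quality threshold (default 0.5).
#' @param min_pref_spikes inclusive minimum mean spikes in the preferred
#'   direction (default 10).
#' @return data.frame with one row per unit: `unit_id`, `total_spikes`,
#'   `dsi`, `fit_quality`, `mu_deg`, `kappa`, `preferred_deg`, `fwhm_deg`,
#'   `avg_spikes_epoch`, `avg_spikes_preferred`, `is_dsgc`, `reason`.
#' @examples
#' r <- gen_mea_responses(20, frac_ds = 0.5, n_epochs = 5, seed = 1)
#' table(classify_units(r)$is_dsgc)
#' @export
classify_units <- function(responses, min_total = 400, dsi_threshold = 0.37,
                           fit_threshold = 0.5, min_pref_spikes = 10) {
  dirs <- responses$directions_deg
  keep <- filter_min_spikes(responses, min_total)
  rows <- lapply(responses$units, function(u) {
    uid <- as.integer(u$unit_id)
    total <- sum(u$counts)
    base <- data.frame(unit_id = uid, total_spikes = total, dsi = NA_real_,
                       fit_quality = NA_real_, mu_deg = NA_real_,
                       kappa = NA_real_, preferred_deg = NA_real_,
                       fwhm_deg = NA_real_,
                       avg_spikes_epoch = mean(u$counts),
                       avg_spikes_preferred = NA_real_,
                       is_dsgc = FALSE, reason = "")
    if (!(uid %in% keep)) {
      base$reason <- "below_min_total_spikes"
      return(base)
    }
    means <- colMeans(u$counts)
    if (all(means == 0)) {
      base$reason <- "no_spikes"
      return(base)
    }
    ds <- compute_dsi(means, dirs)
    fit <- fit_von_mises(means, dirs)
    base$dsi <- ds$dsi
    base$preferred_deg <- ds$preferred_deg
    base$fit_quality <- fit$fit_quality
    base$mu_deg <- fit$mu_deg
    base$kappa <- fit$kappa
    base$fwhm_deg <- if (fit$amplitude > 0 && fit$kappa > 0) {
      tuning_width_fwhm(fit)
    } else NA_real_
    pref_idx <- which(dirs == ds$preferred_deg)
    base$avg_spikes_preferred <- mean(u$counts[, pref_idx])
    pass_dsi <- ds$dsi > dsi_threshold
    pass_fit <- fit$fit_quality > fit_threshold
    pass_pref <- base$avg_spikes_preferred >= min_pref_spikes
    base$is_dsgc <- pass_dsi && pass_fit && pass_pref
    if (!base$is_dsgc) {
      base$reason <- paste(c(if (!pass_dsi) "dsi_below_threshold",
                             if (!pass_fit) "fit_below_threshold",
                             if (!pass_pref) "below_min_preferred_spikes"),
                           collapse = ";")
    }
    base
  })
  do.call(rbind, rows)
}

#' Write directional responses to JSON
#'
#' Layout: `{directions_deg, epoch_dur_s, units: [{unit_id, counts}]}` with
#' `counts` an epoch-by-direction matrix.
#'
#' @param responses a `directional_responses`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_responses_json <- function(responses, path) {
  payload <- list(
    directions_deg = responses$directions_deg,
    epoch_dur_s = responses$epoch_dur_s,
    units = lapply(responses$units, function(u) {
      list(unit_id = u$unit_id, counts = u$counts)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read directional responses from JSON
#'
#' @param path file written by [write_responses_json()] (or any file in the
#'   same layout).
#' @return a `directional_responses`.
#' @export
read_responses_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_counts <- function(cm) {
    if (is.matrix(cm)) cm else do.call(rbind, lapply(cm, unlist))
  }
  units <- if (is.data.frame(raw$units)) {
    lapply(seq_len(nrow(raw$units)), function(i) {
      list(unit_id = raw$units$unit_id[i],
           counts = as_counts(raw$units$counts[[i]]))
    })
  } else {
    lapply(raw$units, function(u) {
      list(unit_id = u$unit_id, counts = as_counts(u$counts))
    })
  }
  structure(list(directions_deg = as.numeric(raw$directions_deg),
                 epoch_dur_s = as.numeric(raw$epoch_dur_s),
                 units = units),
            class = "directional_responses")
}
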