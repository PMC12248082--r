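#' Generate a synthetic starburst-like dendritic arbor
#'
#' Grows a planar, radially symmetric arbor emulating a reconstructed
#' starburst amacrine cell: `n_primary` primary dendrites leave the soma at
#' evenly spread angles and each grows outward as a biased random walk until
#' it reaches `target_radius`. Branch events form a Poisson process along each
#' growing primary path (`rpois(branch_rate * step_len)` events per step, at
#' uniform positions within the step, each marked by its own node); each
#' event spawns a side branch that deflects away and itself grows to the rim
#' without further branching, so the expected number of branch points is
#' `branch_rate` times the summed primary path length and scales linearly
#' with `branch_rate` while the dendritic field area stays fixed by
#' `target_radius`.
#'
#' Dendrite caliber (diameter) tapers linearly from `caliber_taper[1]` at the
#' soma to `caliber_taper[2]` at the rim. With `hypertrophic = TRUE` exactly
#' one primary dendrite is drawn with a proximal-half diameter sampled from
#' (1.2, 2) um, above the 1 um caliber threshold used to call hypertrophic
#' dendrites.
#'
#' @param n_primary number of primary dendrites (>= 1).
#' @param target_radius arbor radius in micrometers (> 0); every branch tip
#'   terminates at this radial distance (never beyond 1.1 x).
#' @param branch_rate expected bifurcations per micrometer of primary path
#'   (>= 0); 0 gives unbranched radial dendrites.
#' @param step_len growth step in micrometers (> 0).
#' @param radial_bias outward-growth weight in \[0, 1\]: 1 grows straight
#'   radial lines, 0 a free planar random walk (capped at a step budget).
#' @param caliber_taper length-2 numeric, proximal and distal dendrite
#'   diameter in micrometers.
#' @param hypertrophic logical; draw one primary with proximal diameter > 1 um.
#' @param z_jitter_sd per-node out-of-plane jitter SD in micrometers.
#' @param soma_radius soma disc radius in micrometers.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   arbors.
#' @return an [arbor]; the soma is node 1 (type 1), dendrites type 3.
#' @examples
#' a <- gen_arbor(n_primary = 4, target_radius = 80, branch_rate = 0.02, seed = 1)
#' count_branch_points(a)
#' @export
gen_arbor <- function(n_primary = 4, target_radius = 150, branch_rate = 0.02,
                      step_len = 2, radial_bias = 0.7,
                      caliber_taper = c(0.8, 0.3), hypertrophic = FALSE,
                      z_jitter_sd = 0.5, soma_radius = 5, seed = NULL) {
  if (n_primary < 1) stop("n_primary must be >= 1")
  if (target_radius <= 0) stop("target_radius must be > 0")
  if (branch_rate < 0) stop("branch_rate must be >= 0")
  if (step_len <= 0) stop("step_len must be > 0")
  if (radial_bias < 0 || radial_bias > 1) stop("radial_bias must be in [0, 1]")
  if (length(caliber_taper) != 2 || any(caliber_taper <= 0)) {
    stop("caliber_taper must be two positive diameters (proximal, distal)")
  }
  if (z_jitter_sd < 0) stop("z_jitter_sd must be >= 0")
  with_seed_opt(seed, {
    grow_arbor(n_primary, target_radius, branch_rate, step_len, radial_bias,
               caliber_taper, hypertrophic, z_jitter_sd, soma_radius)
  })
}

grow_arbor <- function(n_primary, target_radius, branch_rate, step_len,
                       radial_bias, caliber_taper, hypertrophic, z_jitter_sd,
                       soma_radius) {
  turn_sd <- 0.3 # rad per step; wiggle of the walk before radial blending
  max_steps <- ceiling(20 * target_radius / step_len)
  hyper_primary <- if (hypertrophic) sample.int(n_primary, 1) else 0L
  hyper_diam <- if (hypertrophic) stats::runif(1, 1.2, 2.0) else NA_real_

  diam_at <- function(r, primary_idx, on_primary_path) {
    d <- caliber_taper[1] + (caliber_taper[2] - caliber_taper[1]) *
      pmin(r / target_radius, 1)
    if (on_primary_path && primary_idx == hyper_primary && r <= target_radius / 2) {
      d <- hyper_diam
    }
    d
  }

  # node rows accumulate as numeric vectors (id, parent, x, y, z, radius, type)
  rows <- list(c(1, -1, 0, 0, 0, soma_radius, 1))
  next_id <- 2L

  # walk one path outward from (x, y) with heading theta; returns node rows
  # and, for primary paths, the step indices where branch events fired
  grow_path <- function(parent_id, x, y, theta, primary_idx, on_primary_path,
                        allow_branch) {
    path_rows <- list()
    branch_starts <- list() # list of (parent node id, heading)
    for (step in seq_len(max_steps)) {
      theta <- theta + stats::rnorm(1, 0, turn_sd)
      r_cur <- sqrt(x^2 + y^2)
      if (r_cur > 0) {
        radial <- atan2(y, x)
        vx <- (1 - radial_bias) * cos(theta) + radial_bias * cos(radial)
        vy <- (1 - radial_bias) * sin(theta) + radial_bias * sin(radial)
        nv <- sqrt(vx^2 + vy^2)
        if (nv < 1e-12) { vx <- cos(radial); vy <- sin(radial); nv <- 1 }
        theta <- atan2(vy / nv, vx / nv)
      }
      nx <- x + step_len * cos(theta)
      ny <- y + step_len * sin(theta)
      r_new <- sqrt(nx^2 + ny^2)
      done <- FALSE
      if (r_new >= target_radius) {
        # clip the final step so the tip lands exactly on the rim
        nx <- nx * target_radius / r_new
        ny <- ny * target_radius / r_new
        r_new <- target_radius
        done <- TRUE
      }
      # branch events are a Poisson process along the path: events within
      # this step get their own interior nodes, so the expected branch-point
      # count is exactly branch_rate x path length at any step size
      n_events <- if (allow_branch && !done) {
        stats::rpois(1, branch_rate * step_len)
      } else 0L
      if (n_events > 0) {
        for (t in sort(stats::runif(n_events))) {
          bx <- x + t * (nx - x)
          by <- y + t * (ny - y)
          id <- next_id; next_id <<- next_id + 1L
          path_rows[[length(path_rows) + 1L]] <- c(
            id, parent_id, bx, by, stats::rnorm(1, 0, z_jitter_sd),
            diam_at(sqrt(bx^2 + by^2), primary_idx, on_primary_path) / 2, 3)
          side <- theta + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.0)
          branch_starts[[length(branch_starts) + 1L]] <-
            list(parent = id, x = bx, y = by, theta = side)
          parent_id <- id; x <- bx; y <- by
        }
      }
      id <- next_id; next_id <<- next_id + 1L
      path_rows[[length(path_rows) + 1L]] <- c(
        id, parent_id, nx, ny, stats::rnorm(1, 0, z_jitter_sd),
        diam_at(r_new, primary_idx, on_primary_path) / 2, 3)
      parent_id <- id; x <- nx; y <- ny
      if (done) break
    }
    list(rows = path_rows, branches = branch_starts)
  }

  for (k in seq_len(n_primary)) {
    theta0 <- 2 * pi * (k - 1) / n_primary + stats::runif(1, -0.1, 0.1)
    main <- grow_path(1L, 0, 0, theta0, k, TRUE, allow_branch = branch_rate > 0)
    rows <- c(rows, main$rows)
    for (b in main$branches) {
      side <- grow_path(b$parent, b$x, b$y, b$theta, k, FALSE, allow_branch = FALSE)
      rows <- c(rows, side$rows)
    }
  }
  m <- do.call(rbind, rows)
  nodes <- data.frame(id = as.integer(m[, 1]), parent = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      type = as.integer(m[, 7]))
  a <- arbor(nodes)
  attr(a, "hyper_primary") <- hyper_primary
  a
}

#' Genotype presets for the cohort simulator
#'
#' Qualitative presets mirroring the direction of the reported dendrite
#' phenotypes, not their exact magnitudes: the conditional-knockout preset
#' doubles the branch rate of the control and draws a single hypertrophic
#' primary dendrite in 80% of cells; field radius is unchanged.
#'
#' @param genotype `"control"` or `"pten_cko"`.
#' @return named list of [gen_arbor] parameters plus `hypertrophic_prob`.
#' @export
genotype_preset <- function(genotype = c("control", "pten_cko")) {
  genotype <- match.arg(genotype)
  base <- list(n_primary = 4, target_radius = 150, branch_rate = 0.333,
               step_len = 2, radial_bias = 0.7, caliber_taper = c(0.8, 0.3),
               z_jitter_sd = 0.5, hypertrophic_prob = 0)
  if (genotype == "pten_cko") {
    base$branch_rate <- base$branch_rate * 2
    base$hypertrophic_prob <- 0.8
  }
  base
}

#' Generate synaptic puncta along an arbor
#'
#' Emulates presynaptic (synaptophysin) puncta on a starburst dendritic
#' arbor: puncta sit at random positions along dendrite segments, restricted
#' to normalized soma distance >= `inner_boundary` (2/3 reproduces the
#' outer-third output compartment of starburst cells). Position is sampled
#' proportional to dendritic length. Diameters are truncated-normal (> 0) and
#' volume is the sphere volume `pi/6 * d^3`.
#'
#' @param arbor an [arbor] with dendrite nodes.
#' @param n number of puncta.
#' @param inner_boundary normalized soma distance in \[0, 1) below which no
#'   puncta are placed; 0 distributes over the whole arbor.
#' @param diam_mean,diam_sd truncated-normal diameter parameters, micrometers.
#' @param seed integer seed.
#' @return a `puncta_set`: list with `puncta` (data.frame x, y, z, volume),
#'   `soma_center` and `arbor_radial_extent`.
#' @export
gen_puncta <- function(arbor, n, inner_boundary = 2 / 3, diam_mean = 0.8,
                       diam_sd = 0.05, seed = NULL) {
  validate_arbor(arbor)
  if (inner_boundary < 0 || inner_boundary >= 1) {
    stop("inner_boundary must be in [0, 1)")
  }
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0) stop("arbor has no dendrite segments")
  ctr <- soma_center(arbor)
  extent <- radial_extent(arbor)
  tip_dist <- pmax(
    sqrt((seg$x0 - ctr[1])^2 + (seg$y0 - ctr[2])^2 + (seg$z0 - ctr[3])^2),
    sqrt((seg$x1 - ctr[1])^2 + (seg$y1 - ctr[2])^2 + (seg$z1 - ctr[3])^2))
  if (max(tip_dist) < inner_boundary * extent) {
    stop("no dendrite beyond inner_boundary ", inner_boundary,
         "; puncta cannot be placed")
  }
  seg_len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  keep <- seg_len > 0
  seg <- seg[keep, , drop = FALSE]
  seg_len <- seg_len[keep]
  with_seed_opt(seed, {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    attempts <- 0L
    budget <- 1000L * n + 1000L
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > budget) {
        stop("puncta placement failed: could not place ", n,
             " puncta beyond inner_boundary ", inner_boundary)
      }
      i <- sample.int(nrow(seg), 1, prob = seg_len)
      t <- stats::runif(1)
      p <- c(seg$x0[i] + t * (seg$x1[i] - seg$x0[i]),
             seg$y0[i] + t * (seg$y1[i] - seg$y0[i]),
             seg$z0[i] + t * (seg$z1[i] - seg$z0[i]))
      if (sqrt(sum((p - ctr)^2)) / extent >= inner_boundary) {
        placed <- placed + 1L
        pts[placed, ] <- p
      }
    }
    d <- numeric(n)
    for (j in seq_len(n)) {
      repeat {
        dj <- stats::rnorm(1, diam_mean, diam_sd)
        if (dj > 0) break
      }
      d[j] <- dj
    }
    puncta_set(
      data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 volume = pi / 6 * d^3),
      soma_center = ctr, arbor_radial_extent = extent)
  })
}
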