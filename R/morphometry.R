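#' Total dendritic length
#'
#' Sum of Euclidean lengths of all parent-to-child segments with a dendrite
#' endpoint; segments internal to the soma (both endpoints typed soma) are
#' excluded.
#'
#' @param arbor an [arbor].
#' @return length in micrometers; 0 with a warning if the arbor has no
#'   dendrite nodes.
#' @export
total_length <- function(arbor) {
  validate_arbor(arbor)
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0) {
    warning("arbor has no dendrite segments; total length is 0")
    return(0)
  }
  sum(sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2))
}

#' Number of dendritic branch points
#'
#' Dendrite nodes with two or more children. The root/soma never counts as a
#' branch point, however many primary dendrites leave it.
#'
#' @param arbor an [arbor].
#' @return integer count.
#' @export
count_branch_points <- function(arbor) {
  validate_arbor(arbor)
  nodes <- arbor$nodes
  n_children <- table(factor(nodes$parent, levels = nodes$id))
  eligible <- nodes$type == 3L & nodes$parent != -1L
  sum(n_children[as.character(nodes$id[eligible])] >= 2)
}

#' Dendritic field area (convex hull)
#'
#' Area of the 2-D convex hull of the xy positions of all dendrite nodes —
#' the planar field covered by the arbor.
#'
#' @param arbor an [arbor] with at least 3 non-collinear dendrite nodes in
#'   xy projection.
#' @return area in square micrometers.
#' @export
field_area_convex_hull <- function(arbor) {
  validate_arbor(arbor)
  dend <- arbor$nodes[arbor$nodes$type == 3L, , drop = FALSE]
  area <- hull_area(dend$x, dend$y)
  if (nrow(dend) < 3 || area == 0) {
    stop("degenerate geometry: need >= 3 non-collinear dendrite nodes for a hull")
  }
  area
}

#' Sholl intersection profile
#'
#' Counts dendrite crossings of concentric spheres centered on the soma at
#' radii `step, 2 * step, ...` up to the arbor's radial extent. A segment
#' crosses the sphere of radius `r` when its endpoint distances straddle `r`;
#' an endpoint exactly at distance `r` counts as outside the sphere, so a
#' crossing at a node is never counted twice.
#'
#' @param arbor an [arbor].
#' @param step radius increment in micrometers (default 1, the sampling used
#'   for reconstructed cells).
#' @return a `sholl_profile`: list with `radii`, `intersections` and
#'   `radial_extent`.
#' @examples
#' a <- gen_arbor(n_primary = 4, target_radius = 50, branch_rate = 0,
#'                radial_bias = 1, seed = 1)
#' sholl_profile(a)$intersections[1:5]
#' @export
sholl_profile <- function(arbor, step = 1.0) {
  validate_arbor(arbor)
  if (step <= 0) stop("step must be > 0")
  ctr <- soma_center(arbor)
  extent <- radial_extent(arbor)
  radii <- seq(step, extent, by = step)
  seg <- arbor_segments(arbor)
  if (nrow(seg) == 0 || length(radii) == 0) {
    return(structure(list(radii = radii,
                          intersections = integer(length(radii)),
                          radial_extent = extent), class = "sholl_profile"))
  }
  d0 <- sqrt((seg$x0 - ctr[1])^2 + (seg$y0 - ctr[2])^2 + (seg$z0 - ctr[3])^2)
  d1 <- sqrt((seg$x1 - ctr[1])^2 + (seg$y1 - ctr[2])^2 + (seg$z1 - ctr[3])^2)
  lo <- pmin(d0, d1)
  hi <- pmax(d0, d1)
  # crossing at r: min endpoint strictly inside (lo < r), max outside (hi >= r)
  ints <- vapply(radii, function(r) sum(lo < r & hi >= r), integer(1))
  structure(list(radii = radii, intersections = ints, radial_extent = extent),
            class = "sholl_profile")
}

#' Normalize a Sholl profile to 10% spans of radial distance
#'
#' Averages intersection counts over successive 10% spans of the cell's
#' radial extent, making profiles of differently sized arbors comparable.
#' Bin `k` covers radii with `(k - 1) / 10 < r / radial_extent <= k / 10`;
#' an empty bin yields 0.
#'
#' @param profile a `sholl_profile` from [sholl_profile()], or a list with
#'   `radii` and `intersections`.
#' @param radial_extent radial extent in micrometers; defaults to the
#'   profile's own.
#' @return numeric length 10 of mean intersection counts.
#' @export
normalize_sholl <- function(profile, radial_extent = profile$radial_extent) {
  if (is.null(radial_extent) || radial_extent <= 0) {
    stop("radial_extent must be > 0")
  }
  frac <- profile$radii / radial_extent
  vapply(1:10, function(k) {
    sel <- frac > (k - 1) / 10 & frac <= k / 10
    if (!any(sel)) 0 else mean(profile$intersections[sel])
  }, numeric(1))
}

#' Count dendrite self-crossings in single z-planes
#'
#' Counts unordered pairs of non-adjacent dendrite segments (sharing no node)
#' whose xy projections properly cross and whose interpolated z values at the
#' crossing point differ by at most `z_tol` — the computational analogue of
#' counting branch intersections within single z-planes of a confocal stack.
#'
#' @param arbor an [arbor].
#' @param z_tol coplanarity tolerance in micrometers (default 0.5).
#' @return integer count.
#' @export
count_self_crossings <- function(arbor, z_tol = 0.5) {
  validate_arbor(arbor)
  if (z_tol < 0) stop("z_tol must be >= 0")
  seg <- arbor_segments(arbor)
  n <- nrow(seg)
  if (n < 2) return(0L)
  # bucket segments by xy midpoint on a grid at least one segment length
  # wide: any properly crossing pair then lies in the same or an adjacent
  # cell, so candidate pairs shrink from O(n^2) to near-linear
  seg_len_xy <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  cell <- max(seg_len_xy, 1e-6)
  mx <- (seg$x0 + seg$x1) / 2
  my <- (seg$y0 + seg$y1) / 2
  cx <- floor(mx / cell)
  cy <- floor(my / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  coord <- do.call(rbind, lapply(strsplit(names(buckets), " "), as.numeric))
  lookup <- stats::setNames(seq_along(buckets), names(buckets))

  acc_i <- vector("list", 5L * length(buckets))
  acc_j <- vector("list", 5L * length(buckets))
  n_acc <- 0L
  # forward neighbor offsets so every cell pair is visited once
  fwd <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  for (b in seq_along(buckets)) {
    idx <- buckets[[b]]
    if (length(idx) > 1) {
      cmb <- utils::combn(idx, 2)
      n_acc <- n_acc + 1L
      acc_i[[n_acc]] <- cmb[1, ]
      acc_j[[n_acc]] <- cmb[2, ]
    }
    for (off in fwd) {
      nb <- lookup[paste(coord[b, 1] + off[1], coord[b, 2] + off[2])]
      if (is.na(nb)) next
      jdx <- buckets[[nb]]
      n_acc <- n_acc + 1L
      acc_i[[n_acc]] <- rep(idx, times = length(jdx))
      acc_j[[n_acc]] <- rep(jdx, each = length(idx))
    }
  }
  if (n_acc == 0L) return(0L)
  pair_i <- unlist(acc_i, use.names = FALSE)
  pair_j <- unlist(acc_j, use.names = FALSE)
  # drop adjacent segment pairs (sharing a node): touching is branching
  share <- seg$child_id[pair_i] == seg$child_id[pair_j] |
    seg$child_id[pair_i] == seg$parent_id[pair_j] |
    seg$parent_id[pair_i] == seg$child_id[pair_j] |
    seg$parent_id[pair_i] == seg$parent_id[pair_j]
  pair_i <- pair_i[!share]; pair_j <- pair_j[!share]
  if (length(pair_i) == 0) return(0L)

  ax <- seg$x0[pair_i]; ay <- seg$y0[pair_i]
  r1x <- seg$x1[pair_i] - ax; r1y <- seg$y1[pair_i] - ay
  cx2 <- seg$x0[pair_j]; cy2 <- seg$y0[pair_j]
  r2x <- seg$x1[pair_j] - cx2; r2y <- seg$y1[pair_j] - cy2
  denom <- r1x * r2y - r1y * r2x
  ok <- abs(denom) >= 1e-12
  t <- ((cx2 - ax) * r2y - (cy2 - ay) * r2x) / denom
  s <- ((cx2 - ax) * r1y - (cy2 - ay) * r1x) / denom
  proper <- ok & t > 0 & t < 1 & s > 0 & s < 1
  zi <- seg$z0[pair_i] + t * (seg$z1[pair_i] - seg$z0[pair_i])
  zj <- seg$z0[pair_j] + s * (seg$z1[pair_j] - seg$z0[pair_j])
  sum(proper & abs(zi - zj) <= z_tol, na.rm = TRUE)
}

# proper crossing of two xy segments; returns c(t, s) interior parameters or
# NULL when the interiors do not cross
segment_xy_crossing <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  r1x <- bx - ax; r1y <- by - ay
  r2x <- dx - cx; r2y <- dy - cy
  denom <- r1x * r2y - r1y * r2x
  if (abs(denom) < 1e-12) return(NULL) # parallel or collinear: no proper crossing
  t <- ((cx - ax) * r2y - (cy - ay) * r2x) / denom
  s <- ((cx - ax) * r1y - (cy - ay) * r1x) / denom
  if (t <= 0 || t >= 1 || s <= 0 || s >= 1) return(NULL)
  c(t, s)
}

#' Hypertrophic-dendrite classification by maximum caliber
#'
#' Maximum dendrite caliber (diameter, twice the node radius) over dendrite
#' nodes farther than `proximal_exclusion` from the soma center, and whether
#' it exceeds the hypertrophic threshold. The comparison is strict: a
#' caliber of exactly 1 um is not hypertrophic. The proximal exclusion keeps
#' the soma taper from triggering the rule.
#'
#' @param arbor an [arbor].
#' @param threshold caliber threshold in micrometers (default 1).
#' @param proximal_exclusion radius around the soma center ignored when
#'   scanning calibers, micrometers (default 5).
#' @return list with `max_caliber` (micrometers) and `is_hypertrophic`.
#' @export
classify_hypertrophic <- function(arbor, threshold = 1.0, proximal_exclusion = 5.0) {
  validate_arbor(arbor)
  ctr <- soma_center(arbor)
  nodes <- arbor$nodes
  d <- sqrt((nodes$x - ctr[1])^2 + (nodes$y - ctr[2])^2 + (nodes$z - ctr[3])^2)
  sel <- nodes$type == 3L & d > proximal_exclusion
  if (!any(sel)) {
    stop("no dendrite nodes beyond the proximal exclusion of ",
         proximal_exclusion, " um")
  }
  max_caliber <- max(2 * nodes$radius[sel])
  list(max_caliber = max_caliber, is_hypertrophic = max_caliber > threshold)
}

#' Soma cross-sectional area
#'
#' Area of the xy convex hull of soma nodes. A reconstruction with a single
#' soma node yields the disc area `pi * radius^2`; with two soma nodes (or a
#' degenerate collinear hull) the larger disc area of the nodes is used.
#'
#' @param arbor an [arbor] with at least one soma node.
#' @return area in square micrometers.
#' @export
soma_area <- function(arbor) {
  validate_arbor(arbor)
  soma <- arbor$nodes[arbor$nodes$type == 1L, , drop = FALSE]
  if (nrow(soma) == 0) stop("arbor has no soma node")
  if (nrow(soma) >= 3) {
    area <- hull_area(soma$x, soma$y)
    if (area > 0) return(area)
  }
  max(pi * soma$radius^2)
}

#' All single-cell morphometrics at once
#'
#' Convenience wrapper computing the full per-cell metric set: total length,
#' branch points, convex-hull field area, self-crossings, maximum caliber and
#' hypertrophic call, soma area, radial extent, and the Sholl profile with
#' its 10-bin radial-distance normalization.
#'
#' @param arbor an [arbor].
#' @param sholl_step Sholl radius increment, micrometers.
#' @param z_tol self-crossing coplanarity tolerance, micrometers.
#' @return list with all metrics; `sholl` holds the raw profile and
#'   `sholl_normalized` the 10 binned means.
#' @export
morphometry <- function(arbor, sholl_step = 1.0, z_tol = 0.5) {
  caliber <- classify_hypertrophic(arbor)
  sholl <- sholl_profile(arbor, step = sholl_step)
  list(
    total_length = total_length(arbor),
    n_branch_points = count_branch_points(arbor),
    field_area = field_area_convex_hull(arbor),
    n_self_crossings = count_self_crossings(arbor, z_tol = z_tol),
    max_caliber = caliber$max_caliber,
    is_hypertrophic = caliber$is_hypertrophic,
    soma_area = soma_area(arbor),
    radial_extent = sholl$radial_extent,
    sholl = sholl,
    sholl_normalized = normalize_sholl(sholl)
  )
}
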