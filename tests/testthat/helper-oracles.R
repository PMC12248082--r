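# Independent brute-force oracles and fixture builders used across tests.

# Sholl oracle: walk every dendrite segment and every radius explicitly.
# Endpoint exactly at r counts as outside the sphere.
sholl_oracle <- function(arb, step = 1.0) {
  nodes <- arb$nodes
  soma <- nodes[nodes$type == 1L, , drop = FALSE]
  if (nrow(soma) == 0) soma <- nodes[nodes$parent == -1L, , drop = FALSE]
  ctr <- c(mean(soma$x), mean(soma$y), mean(soma$z))
  dist_to <- function(i) sqrt(sum((c(nodes$x[i], nodes$y[i], nodes$z[i]) - ctr)^2))
  extent <- max(vapply(seq_len(nrow(nodes)), dist_to, numeric(1)))
  radii <- seq(step, extent, by = step)
  counts <- integer(length(radii))
  for (row in which(nodes$parent != -1L)) {
    p <- match(nodes$parent[row], nodes$id)
    if (nodes$type[row] == 1L && nodes$type[p] == 1L) next
    d1 <- dist_to(p); d2 <- dist_to(row)
    lo <- min(d1, d2); hi <- max(d1, d2)
    for (k in seq_along(radii)) {
      r <- radii[k]
      if (lo < r && hi >= r) counts[k] <- counts[k] + 1L
    }
  }
  list(radii = radii, intersections = counts, radial_extent = extent)
}

# all-pairs O(n^2) self-crossing oracle with plain scalar loops
crossings_oracle <- function(arb, z_tol = 0.5) {
  nodes <- arb$nodes
  rows <- which(nodes$parent != -1L)
  segs <- list()
  for (row in rows) {
    p <- match(nodes$parent[row], nodes$id)
    if (nodes$type[row] == 1L && nodes$type[p] == 1L) next
    segs[[length(segs) + 1L]] <- list(
      a = c(nodes$x[p], nodes$y[p], nodes$z[p]),
      b = c(nodes$x[row], nodes$y[row], nodes$z[row]),
      ids = c(nodes$id[p], nodes$id[row]))
  }
  n <- length(segs)
  if (n < 2) return(0L)
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(segs[[i]]$ids, segs[[j]]$ids)) > 0) next
      A <- segs[[i]]$a; B <- segs[[i]]$b
      C <- segs[[j]]$a; D <- segs[[j]]$b
      r1 <- B[1:2] - A[1:2]; r2 <- D[1:2] - C[1:2]
      den <- r1[1] * r2[2] - r1[2] * r2[1]
      if (abs(den) < 1e-12) next
      t <- ((C[1] - A[1]) * r2[2] - (C[2] - A[2]) * r2[1]) / den
      s <- ((C[1] - A[1]) * r1[2] - (C[2] - A[2]) * r1[1]) / den
      if (t <= 0 || t >= 1 || s <= 0 || s >= 1) next
      zi <- A[3] + t * (B[3] - A[3])
      zj <- C[3] + s * (D[3] - C[3])
      if (abs(zi - zj) <= z_tol) total <- total + 1L
    }
  }
  total
}

# all-pairs histogram oracle for the density recovery profile
drp_oracle <- function(pattern, bin_width, max_radius) {
  pts <- pattern$points
  win <- pattern$window
  n <- nrow(pts)
  interior <- which(pts$x >= win[1] + max_radius & pts$x <= win[3] - max_radius &
                    pts$y >= win[2] + max_radius & pts$y <= win[4] - max_radius)
  edges <- seq(0, max_radius, by = bin_width)
  if (edges[length(edges)] < max_radius) edges <- c(edges, max_radius)
  counts <- integer(length(edges) - 1)
  for (i in interior) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
      if (d >= max_radius || d == 0) next
      b <- which(d > edges[-length(edges)] & d <= edges[-1])
      counts[b] <- counts[b] + 1L
    }
  }
  ann_area <- pi * (edges[-1]^2 - edges[-length(edges)]^2)
  list(counts = counts, density = counts / (length(interior) * ann_area))
}

# Fisher oracle: explicit enumeration with choose(), exact rationals until
# the final division
fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# straight-line arbor fixtures ----------------------------------------------

# unbranched dendrite of `n` collinear nodes spaced `spacing` um along +x
straight_arbor <- function(n = 10, spacing = 1) {
  nodes <- data.frame(id = seq_len(n + 1),
                      parent = c(-1L, seq_len(n)),
                      x = c(0, seq_len(n) * spacing), y = 0, z = 0,
                      radius = c(5, rep(0.4, n)),
                      type = c(1L, rep(3L, n)))
  arbor(nodes)
}

# soma plus explicit dendrite nodes given as a data.frame(parent, x, y, z)
manual_arbor <- function(dend, soma_radius = 5, dend_radius = 0.4) {
  n <- nrow(dend)
  nodes <- data.frame(id = c(1L, seq_len(n) + 1L),
                      parent = c(-1L, dend$parent),
                      x = c(0, dend$x), y = c(0, dend$y), z = c(0, dend$z),
                      radius = c(soma_radius,
                                 if (is.null(dend$radius)) rep(dend_radius, n)
                                 else dend$radius),
                      type = c(1L, rep(3L, n)))
  arbor(nodes)
}

# random small arbor for oracle-equivalence sweeps
random_test_arbor <- function(seed, max_radius = 40) {
  gen_arbor(n_primary = sample(2:5, 1), target_radius = max_radius,
            branch_rate = stats::runif(1, 0, 0.08), step_len = 2,
            radial_bias = stats::runif(1, 0.4, 1),
            z_jitter_sd = stats::runif(1, 0, 1), seed = seed)
}

# m horizontal x n vertical coplanar grid of disjoint segments hanging off a
# far-away soma stem; every horizontal properly crosses every vertical
grid_crossing_arbor <- function(m, n) {
  # horizontals: y = i (i in 1..m), x from 0.5 to n + 0.5
  # verticals:   x = j (j in 1..n), y from 0.5 to m + 0.5
  rows <- list()
  add <- function(parent, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(parent = parent, x = x, y = y, z = z)
  }
  # stem nodes connect each free segment to the root far below the grid plane
  # (long steep connectors never cross anything in-plane within z_tol)
  next_parent <- 1L
  for (i in seq_len(m)) {
    add(1L, 0.5, i, 50)          # connector drop-in, z far away
    p <- length(rows) + 1L       # id of next node = row index + 1
    add(p, 0.5, i, 0)            # left end, in plane
    add(p + 1L, n + 0.5, i, 0)   # right end
  }
  for (j in seq_len(n)) {
    add(1L, j, 0.5, 50)
    p <- length(rows) + 1L
    add(p, j, 0.5, 0)
    add(p + 1L, j, m + 0.5, 0)
  }
  dend <- do.call(rbind, rows)
  manual_arbor(dend)
}
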