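test_that("total length sums Euclidean segment lengths", {
  # 10 collinear nodes spaced 1 um
  expect_equal(total_length(straight_arbor(10, 1)) - 1, 9)

  # Y-tree: stem to (0,10,0), daughters to (+-5, 20, 0)
  y <- manual_arbor(data.frame(parent = c(1L, 2L, 2L),
                               x = c(0, -5, 5), y = c(10, 20, 20), z = 0))
  expect_equal(total_length(y), 10 + 2 * sqrt(125), tolerance = 1e-9)

  # invariance to node re-indexing (same geometry, permuted ids)
  a <- gen_arbor(3, 40, 0.05, seed = 8)
  nodes <- a$nodes
  new_ids <- c(1L, sample(2:nrow(nodes)) * 10L)
  remap <- stats::setNames(new_ids, nodes$id)
  nodes$id <- new_ids
  nodes$parent <- ifelse(nodes$parent == -1L, -1L,
                         unname(remap[as.character(nodes$parent)]))
  expect_equal(total_length(arbor(nodes)), total_length(a))
})

test_that("soma-to-dendrite stem counts toward length but soma-soma does not", {
  with_soma_arm <- arbor(data.frame(
    id = 1:4, parent = c(-1L, 1L, 2L, 3L),
    x = c(0, 3, 6, 10), y = 0, z = 0,
    radius = c(5, 5, 0.4, 0.4), type = c(1L, 1L, 3L, 3L)))
  # soma-soma edge (0->3) excluded; dendrite edges 3->6->10 included
  expect_equal(total_length(with_soma_arm), 7)
})

test_that("branch points count dendrite nodes with >= 2 children, never the soma", {
  expect_equal(count_branch_points(straight_arbor(10)), 0)

  # soma with 5 unbranched primaries
  star <- manual_arbor(data.frame(parent = rep(1L, 5),
                                  x = cos(2 * pi * (0:4) / 5) * 10,
                                  y = sin(2 * pi * (0:4) / 5) * 10, z = 0))
  expect_equal(count_branch_points(star), 0)

  # perfect binary tree of depth 3 on one primary: 7 internal bifurcations
  dend <- data.frame(parent = 1L, x = 0, y = 10, z = 0) # primary stem, id 2
  next_id <- 2L
  frontier <- data.frame(id = 2L, x = 0, y = 10)
  for (depth in 1:3) {
    nf <- list()
    for (i in seq_len(nrow(frontier))) {
      for (s in c(-1, 1)) {
        x <- frontier$x[i] + s * 10 / depth
        y <- frontier$y[i] + 10
        dend <- rbind(dend, data.frame(parent = frontier$id[i], x = x, y = y, z = 0))
        next_id <- next_id + 1L
        nf[[length(nf) + 1L]] <- data.frame(id = next_id, x = x, y = y)
      }
    }
    frontier <- do.call(rbind, nf)
  }
  btree <- manual_arbor(dend)
  expect_equal(count_branch_points(btree), 7)
})

test_that("convex-hull field area matches simple polygons and ignores interior nodes", {
  square <- manual_arbor(data.frame(parent = c(1L, 1L, 1L, 1L),
                                    x = c(0, 100, 100, 0),
                                    y = c(0, 0, 100, 100), z = 0))
  expect_equal(field_area_convex_hull(square), 10000)

  tri <- manual_arbor(data.frame(parent = c(1L, 1L, 1L),
                                 x = c(0, 100, 0), y = c(0, 0, 100), z = 0))
  expect_equal(field_area_convex_hull(tri), 5000)

  # interior nodes leave the hull unchanged
  square_plus <- manual_arbor(data.frame(parent = c(1L, 1L, 1L, 1L, 1L, 1L),
                                         x = c(0, 100, 100, 0, 50, 30),
                                         y = c(0, 0, 100, 100, 50, 20), z = 0))
  expect_equal(field_area_convex_hull(square_plus), 10000)

  collinear <- manual_arbor(data.frame(parent = c(1L, 1L, 1L),
                                       x = c(1, 2, 3), y = c(1, 2, 3), z = 0))
  expect_error(field_area_convex_hull(collinear), "degenerate")
})

test_that("Sholl profile matches hand-built geometries", {
  # 4 straight radial dendrites of length 50: 4 crossings at every radius
  star <- gen_arbor(n_primary = 4, target_radius = 50, branch_rate = 0,
                    radial_bias = 1, z_jitter_sd = 0, seed = 1)
  prof <- sholl_profile(star, step = 1)
  expect_equal(prof$radii, 1:50)
  # the crossing count at r = radial extent depends on float rounding of the
  # clipped tips; the star geometry pins radii 1..49
  expect_true(all(prof$intersections[prof$radii <= 49] == 4))

  # single dendrite bifurcating at 5 um, daughters to 10 um
  fork <- manual_arbor(data.frame(parent = c(1L, 2L, 2L),
                                  x = c(5, 10, 10), y = c(0, 2, -2), z = 0))
  p2 <- sholl_profile(fork, step = 1)
  r_branch <- 5
  expect_true(all(p2$intersections[p2$radii <= r_branch] == 1))
  expect_true(all(p2$intersections[p2$radii > r_branch + 0.5] == 2))
})

test_that("Sholl normalization averages deciles of radial distance", {
  prof <- list(radii = 1:100, intersections = 1:100, radial_extent = 100)
  expect_equal(normalize_sholl(prof), seq(5.5, 95.5, by = 10))

  const <- list(radii = 1:40, intersections = rep(4L, 40), radial_extent = 40)
  expect_equal(normalize_sholl(const), rep(4, 10))

  # proportionally scaled profiles give identical normalized bins
  small <- list(radii = 1:50, intersections = rep(c(2L, 3L), each = 25),
                radial_extent = 50)
  large <- list(radii = seq(2, 100, by = 2),
                intersections = rep(c(2L, 3L), each = 25), radial_extent = 100)
  expect_equal(normalize_sholl(small), normalize_sholl(large))

  expect_error(normalize_sholl(prof, radial_extent = 0), "radial_extent")
})

test_that("Sholl profile is invariant under rigid motion and re-indexing", {
  a <- gen_arbor(4, 40, 0.06, seed = 21)
  prof_a <- sholl_profile(a)
  th <- 0.7
  rot <- a$nodes
  xr <- rot$x * cos(th) - rot$y * sin(th) + 12
  yr <- rot$x * sin(th) + rot$y * cos(th) - 5
  rot$x <- xr; rot$y <- yr
  prof_r <- sholl_profile(arbor(rot))
  expect_equal(prof_r$intersections, prof_a$intersections)
  expect_equal(prof_r$radial_extent, prof_a$radial_extent, tolerance = 1e-9)
  expect_equal(count_branch_points(arbor(rot)), count_branch_points(a))
  expect_equal(field_area_convex_hull(arbor(rot)), field_area_convex_hull(a),
               tolerance = 1e-9)
})

test_that("self-crossings count coplanar X-crossings only", {
  # two segments forming an X at z = 0, fed by steep out-of-plane connectors
  x_at_z <- function(z_arm) {
    manual_arbor(data.frame(
      parent = c(1L, 2L, 3L, 1L, 5L, 6L),
      x = c(-5, -5, 5, -5, -5, 5),
      y = c(5, 5, 6, 6, 6, 5),
      z = c(50, z_arm, z_arm, 50, 0, 0)))
  }
  expect_equal(count_self_crossings(x_at_z(0)), 1)

  # same X with one arm lifted 5 um out of plane
  expect_equal(count_self_crossings(x_at_z(5), z_tol = 0.5), 0)

  # touching at a shared node is branching, not crossing
  y <- manual_arbor(data.frame(parent = c(1L, 2L, 2L),
                               x = c(0, -5, 5), y = c(10, 20, 20), z = 0))
  expect_equal(count_self_crossings(y), 0)
})

test_that("self-crossings match the m x n closed form on grid fixtures", {
  for (mn in list(c(2, 3), c(4, 4), c(5, 2))) {
    g <- grid_crossing_arbor(mn[1], mn[2])
    expect_equal(count_self_crossings(g), mn[1] * mn[2])
    expect_equal(crossings_oracle(g), mn[1] * mn[2])
  }
})

test_that("hypertrophic classification uses strict > on caliber", {
  thin <- manual_arbor(data.frame(parent = c(1L, 2L, 3L),
                                  x = c(10, 20, 30), y = 0, z = 0,
                                  radius = 0.3))
  res <- classify_hypertrophic(thin)
  expect_equal(res$max_caliber, 0.6)
  expect_false(res$is_hypertrophic)

  fat <- manual_arbor(data.frame(parent = c(1L, 2L, 3L),
                                 x = c(10, 20, 30), y = 0, z = 0,
                                 radius = c(0.3, 0.75, 0.3)))
  res2 <- classify_hypertrophic(fat)
  expect_equal(res2$max_caliber, 1.5)
  expect_true(res2$is_hypertrophic)

  # diameter exactly 1.0 um everywhere is NOT hypertrophic (strict >)
  exact <- manual_arbor(data.frame(parent = c(1L, 2L, 3L),
                                   x = c(10, 20, 30), y = 0, z = 0,
                                   radius = 0.5))
  expect_false(classify_hypertrophic(exact)$is_hypertrophic)

  # nodes inside the proximal exclusion cannot trigger the rule
  prox <- manual_arbor(data.frame(parent = c(1L, 2L),
                                  x = c(3, 30), y = 0, z = 0,
                                  radius = c(2, 0.3)))
  expect_false(classify_hypertrophic(prox)$is_hypertrophic)

  stub <- manual_arbor(data.frame(parent = 1L, x = 2, y = 0, z = 0))
  expect_error(classify_hypertrophic(stub), "proximal exclusion")
})

test_that("soma area handles disc, ring and degenerate cases", {
  single <- straight_arbor(3)
  expect_equal(soma_area(single), pi * 25, tolerance = 1e-9)

  # ring of 8 soma nodes on a 6 um circle: regular octagon, 2*sqrt(2)*r^2
  ring_nodes <- data.frame(
    id = 1:9, parent = c(-1L, rep(1L, 8)),
    x = c(0, 6 * cos(2 * pi * (0:7) / 8)),
    y = c(0, 6 * sin(2 * pi * (0:7) / 8)), z = 0,
    radius = c(3, rep(0.5, 8)), type = 1L)
  ring_nodes <- rbind(ring_nodes,
                      data.frame(id = 10L, parent = 1L, x = 10, y = 0, z = 0,
                                 radius = 0.4, type = 3L))
  ring <- arbor(ring_nodes)
  expect_equal(soma_area(ring), 2 * sqrt(2) * 36, tolerance = 1e-9)

  # two soma nodes fall back to the larger disc
  two <- arbor(data.frame(id = 1:3, parent = c(-1L, 1L, 2L),
                          x = c(0, 4, 10), y = 0, z = 0,
                          radius = c(3, 5, 0.4), type = c(1L, 1L, 3L)))
  expect_equal(soma_area(two), pi * 25, tolerance = 1e-9)
})

test_that("morphometry wrapper returns a coherent metric set", {
  a <- gen_arbor(4, 60, 0.04, seed = 31)
  m <- morphometry(a)
  expect_equal(m$total_length, total_length(a))
  expect_equal(m$n_branch_points, count_branch_points(a))
  expect_equal(m$is_hypertrophic, m$max_caliber > 1)
  expect_length(m$sholl_normalized, 10)
  expect_true(all(m$sholl_normalized >= 0))
  expect_lte(m$radial_extent, 66)
})
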