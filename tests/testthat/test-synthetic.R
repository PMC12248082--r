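test_that("gen_arbor honors its parameter contract", {
  # no bifurcation events possible at rate 0
  a <- gen_arbor(n_primary = 4, target_radius = 60, branch_rate = 0, seed = 1)
  expect_equal(count_branch_points(a), 0)

  # determinism: same params + seed give node-for-node identical SWC output
  p1 <- withr::local_tempfile(fileext = ".swc")
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(gen_arbor(4, 80, 0.03, seed = 99), p1)
  write_swc(gen_arbor(4, 80, 0.03, seed = 99), p2)
  expect_identical(readLines(p1), readLines(p2))

  # tips never overshoot the target radius
  big <- gen_arbor(5, 100, 0.05, radial_bias = 0.4, seed = 3)
  expect_lte(radial_extent(big), 1.1 * 100)

  # straight radial growth: total length = n_primary x target_radius
  flat <- gen_arbor(n_primary = 6, target_radius = 50, branch_rate = 0,
                    radial_bias = 1, z_jitter_sd = 0, seed = 4)
  expect_equal(total_length(flat), 6 * 50, tolerance = 1e-6)

  # hypertrophic flag: exactly one primary with proximal diameter > 1 um
  h <- gen_arbor(4, 80, 0.02, hypertrophic = TRUE, seed = 5)
  cal <- classify_hypertrophic(h)
  expect_true(cal$is_hypertrophic)
  expect_gte(cal$max_caliber, 1.2)
  expect_lte(cal$max_caliber, 2.0)
  plain <- gen_arbor(4, 80, 0.02, hypertrophic = FALSE, seed = 5)
  expect_false(classify_hypertrophic(plain)$is_hypertrophic)

  expect_error(gen_arbor(0, 80), "n_primary")
  expect_error(gen_arbor(4, -1), "target_radius")
  expect_error(gen_arbor(4, 80, radial_bias = 2), "radial_bias")
})

test_that("doubling branch_rate roughly doubles branch points", {
  bp <- function(rate, seeds) {
    vapply(seeds, function(s) {
      count_branch_points(gen_arbor(4, 100, rate, 2, 0.7, seed = s))
    }, numeric(1))
  }
  m1 <- mean(bp(0.02, 1:200))
  m2 <- mean(bp(0.04, 201:400))
  expect_gte(m2 / m1, 1.6)
  expect_lte(m2 / m1, 2.4)
})

test_that("gen_mosaic respects the hard-core constraint and edge cases", {
  m <- gen_mosaic(100, c(300, 300), dmin = 30, seed = 1)
  expect_equal(nrow(m$points), 100)
  expect_gte(min(stats::dist(m$points)), 30)

  empty <- gen_mosaic(0, c(100, 100))
  expect_equal(nrow(empty$points), 0)

  # infeasible packing names dmin and n in the error
  expect_error(gen_mosaic(500, c(100, 100), dmin = 30, seed = 1,
                          max_attempts = 5000),
               "dmin = 30")

  expect_identical(gen_mosaic(50, c(200, 200), dmin = 10, seed = 7)$points,
                   gen_mosaic(50, c(200, 200), dmin = 10, seed = 7)$points)
})

test_that("gen_mea_responses marginal counts are Poisson at the stated mean", {
  r <- gen_mea_responses(1, frac_ds = 1, baseline_rate = 2, ds_amplitude = 20,
                         kappa = 4, n_epochs = 2000, epoch_dur = 3, seed = 10)
  mu <- r$mu_true_deg[1]
  theta <- r$directions_deg * pi / 180
  lam <- 3 * (2 + 20 * exp(4 * (cos(theta - mu * pi / 180) - 1)))
  means <- colMeans(r$units[[1]]$counts)
  se <- sqrt(lam / 2000)
  expect_true(all(abs(means - lam) <= 3 * se))
})

test_that("kappa = 0 removes tuning from DS units", {
  r <- gen_mea_responses(100, frac_ds = 1, baseline_rate = 5, ds_amplitude = 10,
                         kappa = 0, n_epochs = 20, seed = 11)
  dsis <- vapply(r$units, function(u) {
    compute_dsi(colMeans(u$counts), r$directions_deg)$dsi
  }, numeric(1))
  expect_lt(mean(dsis), 0.15)
})

test_that("zero baseline and sharp tuning give DSI near 1", {
  r <- gen_mea_responses(20, frac_ds = 1, baseline_rate = 0, ds_amplitude = 20,
                         kappa = 8, n_epochs = 10, seed = 12)
  dsis <- vapply(r$units, function(u) {
    compute_dsi(colMeans(u$counts), r$directions_deg)$dsi
  }, numeric(1))
  expect_gte(min(dsis), 0.98)
})

test_that("gen_mea_responses validates parameters", {
  expect_error(gen_mea_responses(10, frac_ds = 1.5), "frac_ds")
  expect_error(gen_mea_responses(10, n_directions = 7), "even")
  expect_error(gen_mea_responses(10, kappa = -1), "kappa")
})

test_that("directional responses survive a JSON round-trip", {
  r <- gen_mea_responses(5, frac_ds = 0.4, n_epochs = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_responses_json(r, path)
  r2 <- read_responses_json(path)
  expect_equal(r2$directions_deg, r$directions_deg)
  expect_equal(r2$epoch_dur_s, r$epoch_dur_s)
  for (i in seq_along(r$units)) {
    expect_equal(unname(r2$units[[i]]$counts), unname(r$units[[i]]$counts))
  }
})

test_that("gen_mea_layout counts electrodes from pitch, size and span", {
  acc <- gen_mea_layout(pitch = 60, electrode_side = 21, span = 3800)
  expect_equal(acc$n_rows, 64)
  expect_equal(acc$n_electrodes, 4096)
  expect_equal(gen_mea_layout(100, 20, 520)$n_electrodes, 36)
  expect_equal(gen_mea_layout(100, 50, 100)$n_electrodes, 1)
  expect_error(gen_mea_layout(60, 21, 10), "span")
  # centers form a square grid at the pitch
  d <- sort(unique(acc$centers$x))
  expect_equal(unique(round(diff(d), 9)), 60)
})

test_that("gen_lamination places band mass where requested", {
  lp <- gen_lamination(band_centers = 0.5, band_sd = 0.02, weights = 1,
                       noise_sd = 0, n_samples = 400)
  b <- bin_lamination(lp)
  expect_gte(sum(b[9:12]), 0.95)

  sym <- gen_lamination(band_centers = c(0.3, 0.7), band_sd = 0.05,
                        noise_sd = 0, n_samples = 400)
  bs <- bin_lamination(sym)
  expect_equal(bs, rev(bs), tolerance = 1e-10)

  expect_warning(z <- gen_lamination(band_centers = numeric(0), band_sd = 0.1,
                                     weights = numeric(0), noise_sd = 0),
                 "degenerate")
  expect_true(all(z$intensity == 0))
  expect_error(bin_lamination(z), "total intensity")
})

test_that("gen_puncta places puncta on dendrites beyond the boundary", {
  a <- gen_arbor(4, 100, 0.05, seed = 2)
  ps <- gen_puncta(a, 150, inner_boundary = 2 / 3, seed = 3)
  st <- puncta_stats(ps)
  expect_equal(st$count, 150)
  expect_gte(min(st$normalized_distances), 2 / 3)
  expect_true(all(ps$puncta$volume > 0))

  # diameter filter at the generator's default size keeps nearly everything
  kept <- filter_puncta(ps, 0.5)
  expect_gte(nrow(kept$puncta) / 150, 0.99)

  # no dendrite beyond the boundary: soma outline wider than the dendrites
  wide_soma <- arbor(data.frame(
    id = 1:6, parent = c(-1L, 1L, 1L, 1L, 1L, 5L),
    x = c(0, 20, -20, 0, 0, 0), y = c(0, 0, 0, 20, 2, 4), z = 0,
    radius = c(5, 5, 5, 5, 0.4, 0.4), type = c(1L, 1L, 1L, 1L, 3L, 3L)))
  expect_error(gen_puncta(wide_soma, 5, inner_boundary = 0.9), "inner_boundary")

  expect_identical(gen_puncta(a, 20, seed = 9)$puncta,
                   gen_puncta(a, 20, seed = 9)$puncta)
})
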