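test_that("reference bandwidth follows the href convention and its scaling laws", {
  set.seed(11)
  xy <- matrix(rnorm(200), ncol = 2)
  h <- reference_bandwidth(xy)
  expect_equal(h, 0.5 * (sd(xy[, 1]) + sd(xy[, 2])) * 100^(-1 / 6))
  expect_lt(abs(h - 100^(-1 / 6)), 0.1)       # unit-variance sample
  expect_equal(reference_bandwidth(xy * 10), h * 10)  # scale equivariance
  # larger n, same spread => smaller h
  xy2 <- rbind(xy, xy)
  expect_lt(reference_bandwidth(xy2), h)
  expect_error(reference_bandwidth(matrix(1, 6, 2)), "degenerate")
  expect_error(reference_bandwidth(xy[1:4, ]), "at least 5")
})

test_that("estimate_ud matches the brute-force kernel-sum oracle", {
  set.seed(21)
  grid <- make_grid(c(0, 50), c(0, 40), cell = 2)
  xy <- cbind(runif(7, 5, 45), runif(7, 5, 35))
  ud <- estimate_ud(xy, bandwidth = 4, grid)
  expect_equal(ud$density, ud_oracle(xy, 4, grid), tolerance = 1e-10)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)

  # with a mask removing half the plane, remaining cells renormalize to 1
  mask <- matrix(TRUE, grid$ny, grid$nx)
  mask[, 1:(grid$nx / 2)] <- FALSE
  gm <- make_grid(c(0, 50), c(0, 40), cell = 2, mask = mask)
  udm <- estimate_ud(xy, 4, gm)
  expect_equal(sum(udm$density), 1, tolerance = 1e-9)
  expect_true(all(udm$density[!mask] == 0))
  expect_equal(udm$density, ud_oracle(xy, 4, gm), tolerance = 1e-10)
})

test_that("single-point UD is unimodal with argmax at the containing cell", {
  grid <- make_grid(c(0, 100), c(0, 100), cell = 10)
  ud <- estimate_ud(cbind(47, 33), bandwidth = 8, grid)
  peak <- which(ud$density == max(ud$density), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(4, 5))  # row (y=30-40), col (x=40-50)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
})

test_that("contours take cells in decreasing density order", {
  grid <- make_grid(c(0, 100), c(0, 100), cell = 10)
  ud <- estimate_ud(cbind(50, 50), bandwidth = 1e6, grid)  # ~uniform
  expect_equal(length(ud_contour(ud, 0.5)$cells), 50L)
  expect_equal(length(ud_contour(ud, 1.0)$cells), 100L)

  # two-cell UD {0.8, 0.2}: the 0.8 cell alone covers level 0.5
  g2 <- make_grid(c(0, 2), c(0, 1), cell = 1)
  u2 <- estimate_ud(cbind(0.5, 0.5), 1, g2)
  u2$density <- matrix(c(0.8, 0.2), 1, 2)
  expect_equal(ud_contour(u2, 0.5)$cells, 1L)

  # nesting and monotone mass
  set.seed(5)
  ud3 <- estimate_ud(cbind(runif(20, 20, 80), runif(20, 20, 80)), 8, grid)
  c50 <- ud_contour(ud3, 0.5); c95 <- ud_contour(ud3, 0.95)
  expect_true(all(c50$cells %in% c95$cells))
  expect_gte(sum(ud3$density[c50$cells]), 0.5)
  expect_gte(sum(ud3$density[c95$cells]), 0.95)
})

test_that("volume of intersection is a symmetric overlap index on [0, 1]", {
  grid <- make_grid(c(0, 100), c(0, 100), cell = 5)
  set.seed(31)
  a <- estimate_ud(cbind(runif(15, 10, 50), runif(15, 10, 90)), 8, grid)
  b <- estimate_ud(cbind(runif(15, 50, 90), runif(15, 10, 90)), 8, grid)
  expect_equal(volume_intersection(a, a), 1, tolerance = 1e-12)
  vi <- volume_intersection(a, b)
  expect_equal(vi, volume_intersection(b, a))
  expect_gte(vi, 0); expect_lte(vi, 1)

  # disjoint supports -> 0
  d1 <- a; d1$density <- matrix(0, grid$ny, grid$nx)
  d1$density[, 1:5] <- 1 / (5 * grid$ny)
  d2 <- a; d2$density <- matrix(0, grid$ny, grid$nx)
  d2$density[, 10:14] <- 1 / (5 * grid$ny)
  expect_equal(volume_intersection(d1, d2), 0)

  # analytic half-overlap of two uniform UDs -> 0.5
  u1 <- a; u1$density <- matrix(0, grid$ny, grid$nx)
  u1$density[, 1:10] <- 1 / (10 * grid$ny)
  u2 <- a; u2$density <- matrix(0, grid$ny, grid$nx)
  u2$density[, 6:15] <- 1 / (10 * grid$ny)
  expect_equal(volume_intersection(u1, u2), 0.5, tolerance = 1e-12)

  # different grids refuse to combine
  other <- estimate_ud(cbind(1, 1), 2, make_grid(c(0, 50), c(0, 50), 5))
  expect_error(volume_intersection(a, other), "different grids")
})

test_that("centroid-to-contour distance recovers the short radius of simple shapes", {
  # rasterized disc of radius 30
  grid <- make_grid(c(0, 100), c(0, 100), cell = 2)
  cc <- avoidnull:::grid_centres(grid)
  inside <- outer(cc$y - 50, cc$x - 50, function(dy, dx) dx^2 + dy^2 <= 30^2)
  ud <- estimate_ud(cbind(50, 50), 10, grid)
  ud$density <- inside / sum(inside)
  d <- centroid_contour_distance(ud, level = 1.0)
  expect_lt(abs(d - 30), 2 * grid$cell)

  # elongated rectangle: distance equals the SHORT half-axis
  rect <- outer(cc$y, cc$x, function(y, x) x >= 10 & x <= 90 & y >= 40 & y <= 60)
  ud$density <- rect / sum(rect)
  d2 <- centroid_contour_distance(ud, level = 1.0)
  expect_lt(abs(d2 - 10), 2 * grid$cell)

  # single-cell region: half a cell size
  ud$density <- matrix(0, grid$ny, grid$nx); ud$density[25, 25] <- 1
  expect_equal(centroid_contour_distance(ud, 0.95), grid$cell / 2)
})

test_that("stabilization curve plateaus for a stationary mover and matches full data at n_max", {
  set.seed(41)
  n_full <- 60
  df <- data.frame(id = rep(c("A", "B"), each = n_full),
                   period = rep(1:n_full, 2),
                   x = c(rnorm(n_full, 100, 20), rnorm(n_full, 160, 20)),
                   y = c(rnorm(n_full, 100, 20), rnorm(n_full, 120, 20)))
  tb <- as_sighting_table(df)
  curve <- stabilization_curve(tb, n_values = c(10, 30, n_full), reps = 5,
                               seed = 7, bandwidth = 10, cell = 5)
  expect_equal(curve$n, c(10, 30, n_full))
  # n = full count: unique subsample, zero sd, area equals full-data area
  expect_equal(curve$sd_area[3], 0)
  uds <- avoidnull:::estimate_uds(tb, base_config(cell_size = 5, bandwidth = 10))
  full_area <- mean(vapply(uds, function(u) ud_contour(u, 0.95)$area, numeric(1)))
  expect_equal(curve$mean_area[3], full_area)
  # mean area non-decreasing up to the plateau (stationary movers)
  expect_true(all(diff(curve$mean_area) > -0.05 * curve$mean_area[-3]))
})

test_that("ASCII raster export round-trips header and masses", {
  grid <- make_grid(c(0, 40), c(0, 20), cell = 10)
  ud <- estimate_ud(cbind(15, 15), 8, grid)
  f <- withr::local_tempfile(fileext = ".asc")
  export_ud_ascii(ud, f)
  lines <- readLines(f)
  expect_match(lines[1], "^ncols 4$")
  expect_match(lines[2], "^nrows 2$")
  vals <- scan(text = lines[7:8], quiet = TRUE)
  expect_equal(sum(vals), 1, tolerance = 1e-6)
  # first data row is the TOP of the grid
  expect_equal(matrix(vals, 2, 4, byrow = TRUE)[1, ], ud$density[2, ],
               tolerance = 1e-6)
})
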