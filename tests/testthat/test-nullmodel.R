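test_that("effort polygon area is exact for simple geometries", {
  # 3 non-collinear points, zero buffer: triangle area
  tri <- rbind(c(0, 0), c(1000, 0), c(0, 1000))
  ep <- effort_polygon(tri, buffer = 0)
  expect_equal(ep$area_m2, 0.5 * 1000 * 1000)
  # two points 1 km apart with 1 km buffer: stadium, L*2r + pi*r^2
  seg <- rbind(c(0, 0), c(1000, 0))
  ep2 <- effort_polygon(seg, buffer = 1000)
  expect_equal(ep2$area_km2, (1000 * 2 * 1000 + pi * 1000^2) / 1e6)
  # degenerate geometry with no buffer is an error
  expect_error(effort_polygon(seg, buffer = 0), "degenerate")
  # all constituent points are contained, including the launch point
  set.seed(43)
  pts <- cbind(runif(12, 0, 5000), runif(12, 0, 5000))
  ep3 <- effort_polygon(pts, launch = c(-500, -500), buffer = 1000)
  expect_true(all(effort_contains(ep3, pts[, 1], pts[, 2])))
  expect_true(all(effort_contains(ep3, -500, -500)))
  # buffered containment extends beyond the hull (900 m above a vertex)
  top <- pts[which.max(pts[, 2]), ]
  expect_true(effort_contains(ep3, top[1], top[2] + 900))
  expect_false(effort_contains(ep3, top[1], top[2] + 1100))
  expect_false(effort_contains(ep3, 1e6, 1e6))
})

test_that("roster sizes follow fixed and density modes with clamping", {
  cfg_f <- base_config(n_roster = 64)
  expect_equal(roster_size(cfg_f, n_available = 100), 64L)
  expect_equal(roster_size(cfg_f, n_available = 10), 10L)  # capped
  cfg_d <- base_config(roster_mode = "density", density = 0.45, n_roster = NULL)
  expect_equal(roster_size(cfg_d, n_available = 50, area_km2 = 20), 9L)
  expect_equal(roster_size(cfg_d, n_available = 50, area_km2 = 1), 2L)  # lower clamp
  expect_error(roster_size(cfg_f, n_available = 0), "no available")
  expect_error(roster_size(cfg_d, n_available = 5), "effort polygon")
})

test_that("rosters respect availability and inclusion weights", {
  ids <- sprintf("I%d", 1:5)
  set.seed(47)
  # zero-weight individuals are never sampled
  for (i in 1:50) {
    r <- sample_roster(ids, 3, weights = c(1, 1, 1, 1, 0))
    expect_false("I5" %in% r)
  }
  # uniform weights, n = all available -> the full set
  expect_setequal(sample_roster(ids, 5), ids)
})

test_that("sampled positions follow the UD cell masses and honour restrictions", {
  grid <- make_grid(c(0, 40), c(0, 40), cell = 10)
  set.seed(51)
  ud <- estimate_ud(cbind(runif(10, 5, 35), runif(10, 5, 35)), 10, grid)
  set.seed(52)
  pos <- sample_position(ud, 20000)
  rc <- avoidnull:::cell_of(grid, pos[, 1], pos[, 2])
  emp <- table(factor((rc[, "col"] - 1) * grid$ny + rc[, "row"],
                      levels = seq_len(16)))
  chi <- suppressWarnings(
    chisq.test(as.integer(emp), p = as.vector(ud$density)))
  expect_gt(chi$p.value, 0.001)

  # one-cell UD: every draw lands in that cell
  ud1 <- ud; ud1$density <- matrix(0, 4, 4); ud1$density[2, 3] <- 1
  p1 <- sample_position(ud1, 200)
  expect_true(all(p1[, 1] >= 20 & p1[, 1] <= 30 & p1[, 2] >= 10 & p1[, 2] <= 20))

  # restriction to half the support keeps all draws inside it
  allowed <- rep(c(TRUE, FALSE), each = 8)  # first two columns only
  pr <- sample_position(ud, 500, allowed = allowed)
  expect_true(all(pr[, 1] <= 20))
  expect_error(sample_position(ud1, 1, allowed = c(TRUE, rep(FALSE, 15))),
               "zero UD mass")
})

test_that("replicates are deterministic, availability-true and UD-supported", {
  sw <- small_world_sim(n = 6, seed = 61, n_periods = 30)
  tb <- sw$sim$table
  cfg <- base_config(n_roster = 4)
  uds <- avoidnull:::estimate_uds(tb, cfg)
  av <- derive_availability(tb)
  # force turnover-like windows
  av$first[1] <- 10L; av$last[2] <- 15L
  r1 <- simulate_replicate(uds, av, cfg, seed = 99)
  r2 <- simulate_replicate(uds, av, cfg, seed = 99)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # no one appears outside its window
  for (i in seq_len(nrow(av))) {
    prs <- r1$period_idx[r1$id == av$id[i]]
    expect_true(all(prs >= av$first[i] & prs <= av$last[i]))
  }
  # every position lies in its individual's UD support (kernel support is
  # the whole grid, so check on-grid containment)
  rc <- avoidnull:::cell_of(uds[[1]]$grid, r1$x, r1$y)
  expect_false(anyNA(rc))
  # fixed roster: every period has min(n_roster, n_available) records
  per <- table(r1$period_idx)
  expect_true(all(per <= 4))
})

test_that("effort geometry confines rosters and positions", {
  sw <- small_world_sim(n = 6, seed = 71, n_periods = 20)
  tb <- sw$sim$table
  cfg <- base_config(roster_mode = "density", density = 30000,
                     n_roster = NULL, effort_buffer = 60)
  uds <- avoidnull:::estimate_uds(tb, cfg)
  av <- derive_availability(tb)
  eff <- effort_polygons(tb, buffer = 60)
  r <- simulate_replicate(uds, av, cfg, seed = 5, effort = eff)
  # raster semantics: the CELL a position falls in has its centre inside the
  # polygon (the jitter within a boundary cell may poke past the edge)
  grid <- uds[[1]]$grid
  for (p in unique(r$period_idx)) {
    pl <- eff[[as.character(p)]]
    rows <- r$period_idx == p
    rc <- avoidnull:::cell_of(grid, r$x[rows], r$y[rows])
    cx <- grid$x0 + (rc[, "col"] - 0.5) * grid$cell
    cy <- grid$y0 + (rc[, "row"] - 0.5) * grid$cell
    expect_true(all(effort_contains(pl, cx, cy)))
  }
})

test_that("null distributions cover the observed dyad universe with B values each", {
  sw <- small_world_sim(n = 6, seed = 81, n_periods = 40)
  tb <- sw$sim$table
  cfg <- base_config(n_roster = 5, B = 8)
  uds <- avoidnull:::estimate_uds(tb, cfg)
  av <- derive_availability(tb)
  nul <- null_distributions(uds, av, cfg, gprox = 10, B = 8, seed = 3)
  obs <- association_summary(tb, 10, availability = av)
  expect_equal(paste(nul$dyads$id_a, nul$dyads$id_b),
               paste(obs$dyads$id_a, obs$dyads$id_b))
  expect_equal(dim(nul$hwi), c(nrow(obs$dyads), 8L))
  expect_true(all(nul$hwi >= 0 & nul$hwi <= 1))
  # B = 1 degenerates to a single replicate's HWIs
  n1 <- null_distributions(uds, av, cfg, gprox = 10, B = 1, seed = 3)
  expect_equal(dim(n1$hwi), c(nrow(obs$dyads), 1L))
})

test_that("sweep and null agree at the same gprox, seed and replicate count", {
  sw <- small_world_sim(n = 6, seed = 91, n_periods = 30)
  tb <- sw$sim$table
  cfg <- base_config(n_roster = 5)
  uds <- avoidnull:::estimate_uds(tb, cfg)
  av <- derive_availability(tb)
  swp <- sweep_gprox(uds, av, cfg, candidates = c(10, 20), reps = 6, seed = 7,
                     observed_mean_hwi = 0.01, bound = 50)
  nul10 <- null_distributions(uds, av, cfg, gprox = 10, B = 6, seed = 7)
  nul20 <- null_distributions(uds, av, cfg, gprox = 20, B = 6, seed = 7)
  expect_equal(swp$mean_random_hwi, c(mean(nul10$hwi), mean(nul20$hwi)))
})
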