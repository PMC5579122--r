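# Shared fixture builders and independent oracles.

# Small sighting table from vectors.
tbl_of <- function(id, period, x, y, ...) {
  as_sighting_table(data.frame(id = id, period = period, x = x, y = y, ...,
                               stringsAsFactors = FALSE))
}

# Brute-force Gaussian kernel-sum UD oracle: plain loops over cells and
# points, no masking shortcuts.
ud_oracle <- function(xy, h, grid) {
  cc <- avoidnull:::grid_centres(grid)
  d <- matrix(0, grid$ny, grid$nx)
  for (r in seq_len(grid$ny)) {
    for (c in seq_len(grid$nx)) {
      s <- 0
      for (k in seq_len(nrow(xy))) {
        s <- s + dnorm(cc$x[c] - xy[k, 1], sd = h) *
                 dnorm(cc$y[r] - xy[k, 2], sd = h)
      }
      d[r, c] <- s / nrow(xy) * grid$cell^2
    }
  }
  if (!is.null(grid$mask)) d[!grid$mask] <- 0
  d / sum(d)
}

# Naive per-period double-loop dyad tally oracle.
tally_oracle <- function(table, gprox, mode = "pairwise") {
  ids <- sort(unique(table$id))
  av <- derive_availability(table)
  av <- av[match(ids, av$id), ]
  out <- NULL
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- ids[i]; b <- ids[j]
    jf <- max(av$first[i], av$first[j]); jl <- min(av$last[i], av$last[j])
    if (jf > jl) next
    n_ab <- 0L; y_ab <- 0L; n_a <- 0L; n_b <- 0L
    for (p in jf:jl) {
      ra <- table[table$id == a & table$period_idx == p, ]
      rb <- table[table$id == b & table$period_idx == p, ]
      if (nrow(ra)) n_a <- n_a + 1L
      if (nrow(rb)) n_b <- n_b + 1L
      if (nrow(ra) && nrow(rb)) {
        here <- table[table$period_idx == p, ]
        am <- group_by_proximity(cbind(here$x, here$y), gprox, mode)
        ii <- which(here$id == a); jj <- which(here$id == b)
        if (am[ii, jj]) n_ab <- n_ab + 1L else y_ab <- y_ab + 1L
      }
    }
    out <- rbind(out, data.frame(id_a = a, id_b = b, n_ab = n_ab,
                                 y_ab = y_ab, n_a = n_a, n_b = n_b,
                                 stringsAsFactors = FALSE))
  }
  out
}

# A deterministic stationary world + observed table used by several tests.
small_world_sim <- function(n = 8, seed = 42, n_periods = 50, overlap = 0.3,
                            detection = 0.9, gprox = 10) {
  w <- make_world(n, space_extent = 400, overlap_target = overlap,
                  n_periods = n_periods, seed = seed, ud_sd = 25,
                  gprox = gprox, detection_prob = detection)
  list(world = w, sim = simulate_surveys(w, seed = seed + 1))
}

base_config <- function(...) {
  args <- modifyList(list(gprox_observed = 10, cell_size = 10, bandwidth = 15,
                          min_sightings_ud = 5, B = 50, n_roster = 6,
                          sweep_reps = 10), list(...))
  do.call(study_config, args)
}
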