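test_that("pairwise and chain grouping differ exactly by connectivity", {
  xy <- rbind(c(0, 0), c(0, 3), c(0, 7))
  pw <- group_by_proximity(xy, gprox = 4, mode = "pairwise")
  expect_true(pw[1, 2] && pw[2, 3])
  expect_false(pw[1, 3])
  ch <- group_by_proximity(xy, gprox = 4, mode = "chain")
  expect_true(all(ch[upper.tri(ch)]))

  # chain associations = same connected component (matrix-power oracle)
  set.seed(9)
  for (rep in 1:20) {
    xy <- matrix(runif(2 * 8, 0, 30), ncol = 2)
    adj <- as.matrix(dist(xy)) <= 8; diag(adj) <- FALSE
    reach <- adj
    for (k in 1:8) reach <- (reach %*% (adj + diag(8)) > 0) | reach
    ch <- group_by_proximity(xy, 8, "chain")
    expect_equal(unname(ch), unname(reach & !diag(8) > 0))
    # chain set always contains the pairwise set
    expect_true(all(ch[group_by_proximity(xy, 8, "pairwise")]))
  }

  # single individual: no dyads
  expect_equal(dim(group_by_proximity(matrix(c(1, 1), 1, 2), 5)), c(1L, 1L))
})

test_that("tally_dyads matches a naive per-period double-loop oracle", {
  # hand-built 3-period table: A,B together in 2 periods, apart in 1
  tb <- tbl_of(id = c("A", "B", "A", "B", "A", "B"),
               period = c(1, 1, 2, 2, 3, 3),
               x = c(0, 1, 0, 1, 0, 50), y = 0)
  dy <- tally_dyads(tb, gprox = 5)
  expect_equal(dy$n_ab, 2L)
  expect_equal(dy$y_ab, 1L)
  expect_equal(c(dy$n_a, dy$n_b), c(3L, 3L))

  # a period where only A is sighted contributes to n_a only (and only when
  # it falls inside the joint availability window)
  tb2 <- tbl_of(id = c("A", "B", "A", "B"), period = c(1, 1, 2, 3),
                x = c(0, 1, 0, 40), y = 0)
  dy2 <- tally_dyads(tb2, gprox = 5)
  expect_equal(c(dy2$n_ab, dy2$n_a, dy2$n_b), c(1L, 2L, 1L))

  # randomized tables against the oracle, both modes
  set.seed(17)
  for (rep in 1:5) {
    n_ind <- sample(4:8, 1)
    df <- do.call(rbind, lapply(1:15, function(p) {
      who <- sample(n_ind, sample(0:n_ind, 1))
      if (!length(who)) return(NULL)
      data.frame(id = sprintf("I%d", who), period = p,
                 x = runif(length(who), 0, 40),
                 y = runif(length(who), 0, 40))
    }))
    tb <- as_sighting_table(df)
    for (mode in c("pairwise", "chain")) {
      got <- tally_dyads(tb, gprox = 12, mode = mode)
      want <- tally_oracle(tb, gprox = 12, mode = mode)
      expect_equal(got[c("id_a", "id_b", "n_ab", "y_ab", "n_a", "n_b")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("dyads outside joint availability are omitted", {
  tb <- tbl_of(id = c("A", "A", "B", "B", "C"),
               period = c(1, 5, 6, 9, 5),
               x = c(0, 0, 1, 1, 0.5), y = 0)
  dy <- tally_dyads(tb, gprox = 5)
  expect_false(any(dy$id_a == "A" & dy$id_b == "B"))  # windows [1,5] vs [6,9]
  expect_true(any(dy$id_a == "A" & dy$id_b == "C"))
})

test_that("aggression-flagged records are excluded from tallies", {
  tb <- tbl_of(id = c("A", "B", "A", "B"), period = c(1, 1, 2, 2),
               x = c(0, 1, 0, 1), y = 0,
               aggressive = c(FALSE, FALSE, FALSE, TRUE))
  dy <- tally_dyads(tb, gprox = 5, exclude_col = "aggressive")
  expect_equal(dy$n_ab, 1L)   # period 2's B record removed
})

test_that("HWI conventions agree with the formulas and bound each other", {
  expect_equal(hwi(3, 10, 8, 2), 3 / 14)
  expect_equal(hwi(0, 10, 8, 2), 0)
  expect_equal(hwi(0, 0, 0, 0), 0)      # 0/0 -> 0
  # constant companions: printed caps at 0.5, standard reaches 1
  expect_equal(hwi(7, 7, 7, 0, "printed"), 0.5)
  expect_equal(hwi(7, 7, 7, 0, "standard"), 1)
  expect_error(hwi(-1, 2, 2, 0), "negative")
  # printed <= standard, both in [0, 1], over random valid counts
  set.seed(23)
  for (i in 1:200) {
    n_ab <- rpois(1, 2); y_ab <- rpois(1, 2)
    n_a <- n_ab + y_ab + rpois(1, 3); n_b <- n_ab + y_ab + rpois(1, 3)
    hp <- hwi(n_ab, n_a, n_b, y_ab, "printed")
    hs <- hwi(n_ab, n_a, n_b, y_ab, "standard")
    expect_lte(hp, hs + 1e-12)
    expect_gte(hp, 0); expect_lte(hs, 1)
  }
})

test_that("mean HWI averages over all co-available dyads, zeros included", {
  tb <- tbl_of(id = c("A", "B", "C", "A", "B", "C"),
               period = c(1, 1, 1, 2, 2, 2),
               x = c(0, 1, 50, 0, 30, 60), y = 0)
  s <- association_summary(tb, gprox = 5)
  expect_equal(s$mean_hwi, mean(s$dyads$hwi))
  expect_equal(nrow(s$dyads), 3L)
  # brute-force check
  manual <- tally_oracle(tb, 5)
  expect_equal(s$mean_hwi,
               mean(hwi(manual$n_ab, manual$n_a, manual$n_b, manual$y_ab)))
})

test_that("HWI is non-decreasing in gprox with fixed positions", {
  set.seed(29)
  df <- do.call(rbind, lapply(1:12, function(p) {
    data.frame(id = sprintf("I%d", 1:6), period = p,
               x = runif(6, 0, 50), y = runif(6, 0, 50))
  }))
  tb <- as_sighting_table(df)
  ladder <- c(2, 5, 10, 20, 40)
  for (mode in c("pairwise", "chain")) {
    hw <- vapply(ladder, function(g) mean_hwi(tally_dyads(tb, g, mode)),
                 numeric(1))
    expect_true(all(diff(hw) >= 0))
  }
})

test_that("core restriction keeps sightings only inside the owner's contour", {
  grid <- make_grid(c(0, 100), c(0, 100), cell = 5)
  set.seed(37)
  pa <- cbind(rnorm(40, 30, 8), rnorm(40, 30, 8))
  pb <- cbind(rnorm(40, 70, 8), rnorm(40, 70, 8))
  uds <- list(A = estimate_ud(pa, 8, grid, id = "A"),
              B = estimate_ud(pb, 8, grid, id = "B"))
  tb <- tbl_of(id = c("A", "A", "B"), period = c(1, 2, 1),
               x = c(30, 70, 70), y = c(30, 70, 70))
  core <- restrict_to_core(tb, uds, level = 0.5)
  # A's sighting at its own density peak survives; A's sighting inside B's
  # core (but outside A's) is dropped -- ownership is per-individual
  expect_true(any(core$id == "A" & core$x == 30))
  expect_false(any(core$id == "A" & core$x == 70))
  expect_true(any(core$id == "B"))
  # level 1 is the identity for individuals with UDs
  expect_equal(nrow(restrict_to_core(tb, uds, level = 1)), nrow(tb))
  # individuals without a UD are dropped with a warning
  expect_warning(r2 <- restrict_to_core(tb, uds["A"], 0.5), "without a UD")
  expect_false(any(r2$id == "B"))
})

test_that("hwi_matrix is symmetric and keyed by id", {
  tb <- tbl_of(id = c("A", "B", "A", "B"), period = c(1, 1, 2, 2),
               x = c(0, 1, 0, 40), y = 0)
  m <- hwi_matrix(association_summary(tb, 5))
  expect_equal(m["A", "B"], m["B", "A"])
  expect_equal(m["A", "B"], hwi(1, 2, 2, 1))
})
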