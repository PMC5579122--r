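#' Two-tailed permutation p-values for one dyad
#'
#' `p_avoid` is the proportion of random HWIs less than or equal to the
#' observed value (small when the pair is seen together far less than the
#' null predicts); `p_prefer` is the proportion greater than or equal to it.
#' Both tails use inclusive comparison, directly matching the counting
#' formula \eqn{P = \sum_j [Y_j \le X] / B}; there is no small-sample
#' correction, so ties (common at HWI = 0) make the test conservative.
#'
#' @param random_hwis numeric vector of `B` random HWIs for the dyad.
#' @param observed the dyad's observed HWI.
#' @return named numeric vector `c(p_avoid, p_prefer)`.
#' @export
dyad_pvalues <- function(random_hwis, observed) {
  if (!length(random_hwis)) stop("empty null distribution")
  c(p_avoid = mean(random_hwis <= observed),
    p_prefer = mean(random_hwis >= observed))
}

#' Classify a dyadic relationship
#'
#' `"avoidance"` when at least `1 - alpha` of random HWIs exceed or tie the
#' observed value (`p_avoid <= alpha`), `"preference"` when
#' `p_prefer <= alpha`, `"random"` otherwise. Because
#' `p_avoid + p_prefer >= 1`, both tails cannot fire at `alpha < 0.5`;
#' avoidance is tested first.
#'
#' @param p_avoid,p_prefer tail probabilities (vectorized).
#' @param alpha significance level in (0, 0.5].
#' @return character vector in `{"avoidance", "random", "preference"}`.
#' @export
classify <- function(p_avoid, p_prefer, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 0.5)
  ifelse(p_avoid <= alpha, "avoidance",
         ifelse(p_prefer <= alpha, "preference", "random"))
}

#' Per-dyad permutation inference
#'
#' Matches the observed association summary against the null distribution
#' over their (identical) dyad universe, drops dyads where either member has
#' fewer than `min_sightings_classify` total sightings (post-hoc selection:
#' the null is optimized with as many individuals as possible, but reliable
#' classification needs more data per individual), and returns per-dyad
#' p-values, classification and home-range overlap annotations.
#'
#' @param observed an [association_summary()].
#' @param null a [null_distributions()] object on the same dyad universe.
#' @param min_sightings_classify post-hoc per-individual sighting threshold.
#' @param alpha significance level.
#' @param uds optional named list of `ud` objects; when supplied, each dyad
#'   is annotated with its 95% and 50% volume-of-intersection overlap.
#' @param p_adjust optional multiple-testing correction applied to each tail
#'   across dyads (a [stats::p.adjust()] method, e.g. `"BH"`); default none,
#'   classification uses raw tail probabilities.
#' @return data frame of class `dyad_results`: one row per classified dyad
#'   with ids, counts, observed HWI, `p_avoid`, `p_prefer`,
#'   `classification`, `vi_95`, `vi_50` and the joint availability span.
#' @export
run_inference <- function(observed, null, min_sightings_classify = 0,
                          alpha = 0.05, uds = NULL, p_adjust = NULL) {
  dy <- observed$dyads
  key_obs <- paste(dy$id_a, dy$id_b)
  key_null <- paste(null$dyads$id_a, null$dyads$id_b)
  if (!identical(sort(key_obs), sort(key_null))) {
    stop("observed and null dyad universes differ")
  }
  H <- null$hwi[match(key_obs, key_null), , drop = FALSE]
  counts <- observed$counts
  keep <- counts[dy$id_a] >= min_sightings_classify &
    counts[dy$id_b] >= min_sightings_classify
  dy <- dy[keep, , drop = FALSE]
  H <- H[keep, , drop = FALSE]
  p_avoid <- rowMeans(H <= dy$hwi)
  p_prefer <- rowMeans(H >= dy$hwi)
  if (!is.null(p_adjust)) {
    p_avoid <- stats::p.adjust(p_avoid, method = p_adjust)
    p_prefer <- stats::p.adjust(p_prefer, method = p_adjust)
  }
  vi95 <- vi50 <- rep(NA_real_, nrow(dy))
  if (!is.null(uds)) {
    for (i in seq_len(nrow(dy))) {
      a <- uds[[dy$id_a[i]]]; b <- uds[[dy$id_b[i]]]
      if (!is.null(a) && !is.null(b)) {
        vi95[i] <- vi_at_level(a, b, 0.95)
        vi50[i] <- vi_at_level(a, b, 0.50)
      }
    }
  }
  out <- data.frame(
    id_a = dy$id_a, id_b = dy$id_b,
    n_ab = dy$n_ab, y_ab = dy$y_ab, n_a = dy$n_a, n_b = dy$n_b,
    hwi_obs = dy$hwi, p_avoid = p_avoid, p_prefer = p_prefer,
    classification = classify(p_avoid, p_prefer, alpha),
    vi_95 = vi95, vi_50 = vi50,
    joint_first = dy$joint_first, joint_last = dy$joint_last,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("dyad_results", "data.frame")
  out
}

#' Rank avoidances by home-range overlap
#'
#' Among classified avoidance dyads, a pair sharing most of its home range
#' yet never associating is a stronger avoidance than a pair that barely
#' overlaps. Adds a `strength` column (the pair's VI) and a `strength_rank`
#' over avoidance dyads, VI descending, ties broken by dyad ids.
#'
#' @param results a `dyad_results` data frame with VI annotations.
#' @param vi_col which overlap column measures strength (default `"vi_95"`).
#' @return `results` with `strength` and `strength_rank` columns, avoidance
#'   rows ordered first by descending strength.
#' @export
avoidance_strength <- function(results, vi_col = "vi_95") {
  vi <- results[[vi_col]]
  is_avoid <- results$classification == "avoidance"
  results$strength <- ifelse(is_avoid, vi, NA_real_)
  results$strength_rank <- NA_integer_
  if (any(is_avoid)) {
    ord <- order(-vi[is_avoid], results$id_a[is_avoid], results$id_b[is_avoid])
    results$strength_rank[which(is_avoid)[ord]] <- seq_len(sum(is_avoid))
  }
  ord_all <- order(!is_avoid, results$strength_rank, results$id_a, results$id_b)
  out <- results[ord_all, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classification stability under sighting subsampling
#'
#' How many sightings per individual are enough to classify dyads reliably?
#' For each subsample size `n`, draws `n` sightings per individual (from the
#' reference set of individuals with at least `max(sightings_grid)`
#' sightings), re-runs UD estimation, the null model and classification, and
#' compares against the full-data run: Spearman correlation of the dyadic
#' avoidance-tail p-values, plus type I (newly significant) and type II
#' (lost) error counts, separately for preferences and avoidances. Common
#' random numbers are used across subsample sizes, so `n` equal to the full
#' count reproduces the reference run exactly.
#'
#' @param table a `sighting_table`.
#' @param config a [study_config()]; the null grouping distance is
#'   `config$gprox_null` (no per-subsample recalibration).
#' @param sightings_grid increasing subsample sizes.
#' @param reps null replicates per run (default 100).
#' @param seed RNG seed.
#' @param effort optional effort polygons.
#' @return data frame of class `stability_report`: per subsample size, the
#'   Spearman correlation and the four error counts.
#' @export
stability_report <- function(table, config, sightings_grid, reps = 100,
                             seed = config$seed, effort = NULL) {
  counts <- sighting_counts(table)
  n_max <- max(sightings_grid)
  ref_ids <- names(counts)[counts >= n_max]
  if (length(ref_ids) < 2L) stop("fewer than 2 individuals reach max(sightings_grid)")
  tbl_ref <- filter_min_sightings(table, n_max)
  run_once <- function(tbl) {
    uds <- estimate_uds(tbl, config)
    av <- derive_availability(tbl)
    if (config$roster_mode == "fixed" && is.null(config$n_roster)) {
      config$n_roster <- default_roster(tbl)
    }
    obs <- association_summary(tbl, config$gprox_observed,
                               config$grouping_mode, av,
                               config$hwi_convention)
    gp <- config$gprox_null %||% config$gprox_observed
    nul <- null_distributions(uds, av, config, gp, B = reps, seed = seed,
                              effort = effort)
    run_inference(obs, nul, min_sightings_classify = 0, alpha = config$alpha)
  }
  full <- run_once(tbl_ref)
  key_full <- paste(full$id_a, full$id_b)
  set.seed(seed)
  sub_seeds <- child_seeds(seed + 1, length(sightings_grid))
  rows <- lapply(seq_along(sort(sightings_grid)), function(k) {
    n <- sort(sightings_grid)[k]
    set.seed(sub_seeds[k])
    sub <- do.call(rbind, lapply(split(seq_len(nrow(tbl_ref)), tbl_ref$id),
                                 function(i) {
      tbl_ref[sort(sample(i, min(n, length(i)))), , drop = FALSE]
    }))
    sub <- as_sighting_table(as.data.frame(sub),
                             period_index = attr(tbl_ref, "period_index"))
    res <- run_once(sub)
    key_sub <- paste(res$id_a, res$id_b)
    common <- intersect(key_full, key_sub)
    f <- full[match(common, key_full), ]
    s <- res[match(common, key_sub), ]
    rho <- suppressWarnings(
      stats::cor(s$p_avoid, f$p_avoid, method = "spearman"))
    if (is.na(rho) && all(s$p_avoid == f$p_avoid)) rho <- 1
    err <- function(class) {
      c(type1 = sum(s$classification == class & f$classification != class),
        type2 = sum(f$classification == class & s$classification != class))
    }
    ep <- err("preference"); ea <- err("avoidance")
    data.frame(n = n, spearman = rho,
               type1_pref = ep["type1"], type2_pref = ep["type2"],
               type1_avoid = ea["type1"], type2_avoid = ea["type2"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("stability_report", "data.frame")
  out
}

# Estimate one UD per individual on a shared grid, per the configuration.
estimate_uds <- function(table, config, grid = NULL) {
  by_id <- split(table[, c("x", "y")], table$id)
  href <- identical(config$bandwidth, "href")
  bws <- if (href) {
    vapply(by_id, reference_bandwidth, numeric(1L))
  } else {
    stats::setNames(rep(config$bandwidth, length(by_id)), names(by_id))
  }
  if (is.null(grid)) {
    grid <- grid_from_points(table, cell = config$cell_size,
                             bandwidth = max(bws))
  }
  uds <- lapply(names(by_id), function(id) {
    estimate_ud(by_id[[id]], bws[[id]], grid, id = id)
  })
  stats::setNames(uds, names(by_id))
}
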