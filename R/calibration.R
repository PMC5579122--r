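#' Admissible upper bound for the null grouping distance
#'
#' The minimum, over individuals, of the centroid-to-contour distance of the
#' 95% home range. Candidate null grouping distances beyond this bound would
#' group individuals across more than a home-range radius and are not
#' biologically plausible, so the calibration sweep rejects them.
#'
#' @param uds named list of `ud` objects.
#' @param level contour level (default 0.95).
#' @return bound in metres.
#' @export
admissible_gprox_bound <- function(uds, level = 0.95) {
  min(vapply(uds, centroid_contour_distance, numeric(1L), level = level))
}

#' Build a sweep table from precomputed means
#'
#' Assembles a calibration sweep table from candidate grouping distances and
#' their mean random HWIs (e.g. values computed elsewhere or re-entered from
#' a report), ready for [select_gprox()].
#'
#' @param gprox numeric vector of candidate distances (strictly increasing).
#' @param mean_random_hwi mean random HWI per candidate.
#' @param observed_mean_hwi observed population mean HWI.
#' @param n_reps replicates behind each mean (recycled).
#' @return object of class `sweep_table` (a data frame with attributes
#'   `observed_mean_hwi` and optionally `bound`).
#' @export
sweep_table <- function(gprox, mean_random_hwi, observed_mean_hwi,
                        n_reps = NA_integer_) {
  stopifnot(length(gprox) == length(mean_random_hwi),
            !is.unsorted(gprox, strictly = TRUE))
  structure(data.frame(gprox = gprox, mean_random_hwi = mean_random_hwi,
                       n_reps = n_reps),
            observed_mean_hwi = observed_mean_hwi,
            class = c("sweep_table", "data.frame"))
}

#' @export
print.sweep_table <- function(x, ...) {
  obs <- attr(x, "observed_mean_hwi")
  cat("<sweep_table> observed mean HWI: ", format(obs), "\n", sep = "")
  sel <- select_gprox(x)
  df <- data.frame(gprox = x$gprox,
                   mean_random_hwi = format(x$mean_random_hwi),
                   selected = ifelse(x$gprox == sel, "*", ""))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Calibration sweep over candidate grouping distances
#'
#' For each candidate `gprox`, computes the mean random HWI over `reps`
#' null-model replicates, using common random numbers: the same simulated
#' positions are tallied at every candidate, so the sweep column is exactly
#' non-decreasing in `gprox` (a larger radius can only add associations).
#' Candidates beyond the admissible bound are rejected with a message.
#'
#' @inheritParams null_distributions
#' @param candidates candidate distances in metres; defaults to multiples of
#'   the grid cell size up to the admissible bound.
#' @param reps replicates per candidate (default `config$sweep_reps`).
#' @param observed_mean_hwi observed population mean HWI (stored for
#'   selection).
#' @param bound admissible upper bound; defaults to
#'   [admissible_gprox_bound()] of the UDs.
#' @return a [sweep_table()].
#' @export
sweep_gprox <- function(uds, availability, config, candidates = NULL,
                        reps = config$sweep_reps, seed = config$seed,
                        observed_mean_hwi = NA_real_, effort = NULL,
                        bound = NULL) {
  if (is.null(bound)) bound <- admissible_gprox_bound(uds)
  if (is.null(candidates)) {
    k <- floor(bound / config$cell_size)
    # when even one grid increment exceeds the bound, sweep the bound itself
    candidates <- if (k >= 1) config$cell_size * seq_len(k) else bound
  }
  candidates <- sort(unique(candidates))
  bad <- candidates > bound
  if (any(bad)) {
    message("rejecting ", sum(bad), " candidate(s) beyond the admissible ",
            "centroid-to-contour bound of ", signif(bound, 4), " m")
    candidates <- candidates[!bad]
  }
  if (!length(candidates)) stop("no admissible gprox candidates")
  st <- null_state(uds, availability, config, effort)
  dyads <- dyad_universe(st$av)
  seeds <- child_seeds(seed, reps)
  acc <- numeric(length(candidates))
  for (b in seq_len(reps)) {
    set.seed(seeds[b])
    pl <- sim_replicate_core(st)
    hw <- tally_multi_gprox(pl, st$av, st$n_periods, candidates,
                            config$grouping_mode, dyads,
                            config$hwi_convention)
    acc <- acc + colMeans(hw)
  }
  out <- sweep_table(candidates, acc / reps, observed_mean_hwi,
                     n_reps = reps)
  attr(out, "bound") <- bound
  out
}

# HWI matrix (dyads x candidates) for one replicate, reusing per-period
# distance matrices across candidates (common random numbers).
tally_multi_gprox <- function(period_list, availability, n_periods,
                              candidates, mode, dyads, convention) {
  ids <- availability$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  nc <- length(candidates)
  A <- array(0L, c(n, n, nc))
  Y <- array(0L, c(n, n, nc))
  pres <- matrix(FALSE, n, n_periods)
  for (pname in names(period_list)) {
    p <- as.integer(pname)
    rec <- period_list[[pname]]
    here <- idx[rec$ids]
    keep <- !is.na(here)
    here <- here[keep]
    pres[cbind(here, rep(p, length(here)))] <- TRUE
    if (length(here) < 2L) next
    dmat <- as.matrix(stats::dist(rec$xy[keep, , drop = FALSE]))
    for (k in seq_len(nc)) {
      assoc <- assoc_from_dist(dmat, candidates[k], mode)
      A[here, here, k] <- A[here, here, k] + assoc
      Y[here, here, k] <- Y[here, here, k] + (!assoc)
    }
  }
  ia <- idx[dyads$id_a]; ib <- idx[dyads$id_b]
  cum <- if (n_periods == 1L) matrix(as.numeric(pres), n, 1L)
         else t(apply(pres, 1L, cumsum))
  n_a <- cum[cbind(ia, dyads$joint_last)] -
    ifelse(dyads$joint_first > 1L,
           cum[cbind(ia, pmax(dyads$joint_first - 1L, 1L))], 0)
  n_b <- cum[cbind(ib, dyads$joint_last)] -
    ifelse(dyads$joint_first > 1L,
           cum[cbind(ib, pmax(dyads$joint_first - 1L, 1L))], 0)
  out <- matrix(NA_real_, nrow(dyads), nc)
  for (k in seq_len(nc)) {
    out[, k] <- hwi(A[, , k][cbind(ia, ib)], n_a, n_b,
                    Y[, , k][cbind(ia, ib)], convention)
  }
  out
}

#' Select the null grouping distance matching observed sociability
#'
#' Picks the candidate whose mean random HWI is closest (minimum absolute
#' difference) to the observed population mean HWI; exact ties break toward
#' the smaller distance. The selected value is then used for the final
#' full-size null run.
#'
#' @param sweep a [sweep_table()].
#' @param observed_mean_hwi observed mean HWI; defaults to the value stored
#'   in the sweep table.
#' @return selected gprox in metres.
#' @export
select_gprox <- function(sweep, observed_mean_hwi = NULL) {
  obs <- observed_mean_hwi %||% attr(sweep, "observed_mean_hwi")
  if (is.null(obs) || is.na(obs)) stop("no observed mean HWI to match")
  if (!nrow(sweep)) stop("empty sweep table")
  d <- abs(sweep$mean_random_hwi - obs)
  # ties (to numerical precision) break toward the smaller gprox
  best <- which(d <= min(d) + 1e-12)
  sweep$gprox[best[1L]]
}
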