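#' Group individuals by spatial proximity within one sampling period
#'
#' In `"pairwise"` mode two individuals associate iff their Euclidean
#' distance is at most `gprox`. In `"chain"` mode all individuals in the same
#' connected component of the graph linking pairs within `gprox` associate
#' (the chain rule used for species observed in fluid groups, e.g. a 10 m
#' chain rule for dolphins).
#'
#' @param xy two-column coordinate matrix, one row per individual present in
#'   the period.
#' @param gprox grouping distance in metres (> 0).
#' @param mode `"pairwise"` or `"chain"`.
#' @return symmetric logical matrix (`FALSE` diagonal): `[i, j]` is `TRUE`
#'   iff individuals `i` and `j` are associated this period.
#' @export
group_by_proximity <- function(xy, gprox, mode = c("pairwise", "chain")) {
  mode <- match.arg(mode)
  stopifnot(gprox > 0)
  n <- nrow(xy)
  if (n < 2L) return(matrix(FALSE, n, n))
  adj <- as.matrix(stats::dist(xy)) <= gprox
  diag(adj) <- FALSE
  if (mode == "chain") {
    comp <- components_of(adj)
    adj <- outer(comp, comp, "==")
    diag(adj) <- FALSE
  }
  adj
}

# Association matrix from a per-period distance matrix (already computed);
# used on the hot path of the null model so distances are reused across
# candidate gprox values.
assoc_from_dist <- function(dmat, gprox, mode) {
  adj <- dmat <= gprox
  diag(adj) <- FALSE
  if (mode == "chain") {
    comp <- components_of(adj)
    adj <- outer(comp, comp, "==")
    diag(adj) <- FALSE
  }
  adj
}

#' Tally dyadic association counts
#'
#' For every pair of individuals with overlapping availability windows,
#' accumulates over the periods inside *both* windows: `n_ab` (periods both
#' sighted and associated), `y_ab` (both sighted, not associated), and
#' `n_a`, `n_b` (sightings of each member within the joint window). Dyads
#' whose windows do not overlap are omitted -- they never had the temporal
#' opportunity to associate.
#'
#' @param table a `sighting_table`.
#' @param gprox grouping distance in metres.
#' @param mode `"pairwise"` or `"chain"` (see [group_by_proximity()]).
#' @param availability availability windows; defaults to
#'   [derive_availability()] of `table`. Supply the observed-data windows
#'   when tallying simulated tables so both analyses share a dyad universe.
#' @param exclude_col optional name of a logical column marking records to
#'   drop before tallying (e.g. sightings during observed aggression, so
#'   that close proximity reflects social tolerance).
#' @return data frame with one row per co-available dyad: `id_a`, `id_b`
#'   (sorted), `n_ab`, `y_ab`, `n_a`, `n_b`, `joint_first`, `joint_last`.
#' @export
tally_dyads <- function(table, gprox, mode = c("pairwise", "chain"),
                        availability = NULL, exclude_col = NULL) {
  mode <- match.arg(mode)
  if (!is.null(exclude_col) && exclude_col %in% names(table)) {
    table <- table[!isTRUE_vec(table[[exclude_col]]), , drop = FALSE]
  }
  if (is.null(availability)) availability <- derive_availability(table)
  n_periods <- attr(availability, "n_periods") %||%
    length(attr(table, "period_index"))
  period_list <- split_periods(table)
  tally_core(period_list, availability, n_periods, gprox, mode)
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

# table -> list of list(ids, xy) keyed by period index (as character)
split_periods <- function(table) {
  sp <- split(seq_len(nrow(table)), table$period_idx)
  lapply(sp, function(i) list(ids = table$id[i],
                              xy = cbind(table$x[i], table$y[i])))
}

# Shared tally engine for observed tables and simulated replicates.
# period_list: named list (names = period index) of list(ids, xy).
tally_core <- function(period_list, availability, n_periods, gprox, mode,
                       dyads = NULL) {
  ids <- availability$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  A <- matrix(0L, n, n)   # both sighted, associated
  Y <- matrix(0L, n, n)   # both sighted, not associated
  pres <- matrix(FALSE, n, n_periods)
  for (pname in names(period_list)) {
    p <- as.integer(pname)
    rec <- period_list[[pname]]
    here <- idx[rec$ids]
    keep <- !is.na(here)
    here <- here[keep]
    pres[cbind(here, rep(p, length(here)))] <- TRUE
    if (length(here) < 2L) next
    assoc <- group_by_proximity(rec$xy[keep, , drop = FALSE], gprox, mode)
    A[here, here] <- A[here, here] + assoc
    Y[here, here] <- Y[here, here] + (!assoc)
  }
  diag(Y) <- 0L
  if (is.null(dyads)) dyads <- dyad_universe(availability)
  ia <- idx[dyads$id_a]; ib <- idx[dyads$id_b]
  cum <- if (n_periods == 1L) matrix(as.numeric(pres), n, 1L)
         else t(apply(pres, 1L, cumsum))
  win_count <- function(i, lo, hi) {
    cum[cbind(i, hi)] - ifelse(lo > 1L, cum[cbind(i, pmax(lo - 1L, 1L))], 0L)
  }
  data.frame(
    id_a = dyads$id_a, id_b = dyads$id_b,
    n_ab = A[cbind(ia, ib)], y_ab = Y[cbind(ia, ib)],
    n_a = win_count(ia, dyads$joint_first, dyads$joint_last),
    n_b = win_count(ib, dyads$joint_first, dyads$joint_last),
    joint_first = dyads$joint_first, joint_last = dyads$joint_last,
    stringsAsFactors = FALSE
  )
}

# All unordered pairs with non-empty joint availability, with the joint
# window bounds. id_a < id_b.
dyad_universe <- function(availability) {
  av <- availability[order(availability$id), , drop = FALSE]
  n <- nrow(av)
  if (n < 2L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      joint_first = integer(0), joint_last = integer(0)))
  }
  cmb <- utils::combn(n, 2L)
  jf <- pmax(av$first[cmb[1L, ]], av$first[cmb[2L, ]])
  jl <- pmin(av$last[cmb[1L, ]], av$last[cmb[2L, ]])
  keep <- jf <= jl
  data.frame(id_a = av$id[cmb[1L, keep]], id_b = av$id[cmb[2L, keep]],
             joint_first = jf[keep], joint_last = jl[keep],
             stringsAsFactors = FALSE)
}

#' Half-weight association index
#'
#' Two conventions are available. The `"printed"` convention is
#' \deqn{HWI = N_{ab} / (N_{ab} + 0.5 (N_a + N_b) + Y_{ab})}
#' with \eqn{N_a, N_b} the *total* sightings of each member inside the joint
#' availability window; it caps at 0.5 for constant companions. The
#' `"standard"` convention replaces \eqn{N_a, N_b} by the sightings of each
#' member *without* the other,
#' \eqn{N_{ab} / (N_{ab} + Y_{ab} + 0.5((N_a - N_{ab} - Y_{ab}) + (N_b - N_{ab} - Y_{ab})))},
#' and reaches 1 for constant companions. 0/0 is defined as 0.
#'
#' @param n_ab,n_a,n_b,y_ab dyadic counts (vectorized).
#' @param convention `"printed"` (default) or `"standard"`.
#' @return HWI values in \[0, 1\].
#' @export
hwi <- function(n_ab, n_a, n_b, y_ab, convention = c("printed", "standard")) {
  convention <- match.arg(convention)
  if (any(c(n_ab, n_a, n_b, y_ab) < 0)) stop("negative association counts")
  den <- if (convention == "printed") {
    n_ab + 0.5 * (n_a + n_b) + y_ab
  } else {
    n_ab + y_ab + 0.5 * ((n_a - n_ab - y_ab) + (n_b - n_ab - y_ab))
  }
  out <- ifelse(den > 0, n_ab / den, 0)
  as.numeric(out)
}

#' Observed association summary
#'
#' Tallies dyadic counts and computes per-dyad HWIs plus the population mean
#' HWI over all temporally co-available dyads (zeros included) -- the
#' sociability measure the null model is calibrated against.
#'
#' @inheritParams tally_dyads
#' @param convention HWI convention, see [hwi()].
#' @return object of class `association_summary`: list with `dyads` (count
#'   table plus an `hwi` column), `mean_hwi`, `gprox`, `mode`, `convention`,
#'   and per-individual total sighting `counts`.
#' @export
association_summary <- function(table, gprox, mode = c("pairwise", "chain"),
                                availability = NULL,
                                convention = c("printed", "standard"),
                                exclude_col = NULL) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  if (is.null(availability)) availability <- derive_availability(table)
  dy <- tally_dyads(table, gprox, mode, availability, exclude_col)
  dy$hwi <- hwi(dy$n_ab, dy$n_a, dy$n_b, dy$y_ab, convention)
  structure(list(dyads = dy, mean_hwi = mean_hwi(dy, convention),
                 gprox = gprox, mode = mode, convention = convention,
                 availability = availability,
                 counts = sighting_counts(table)),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat("<association_summary> ", nrow(x$dyads), " co-available dyads, gprox ",
      x$gprox, " m (", x$mode, "), mean HWI ", signif(x$mean_hwi, 4), "\n",
      sep = "")
  invisible(x)
}

#' Population mean HWI
#'
#' Arithmetic mean HWI over all dyads with non-empty joint availability,
#' zeros included.
#'
#' @param dyads a dyadic count data frame (from [tally_dyads()]) or an
#'   `association_summary`.
#' @param convention HWI convention, see [hwi()].
#' @return mean HWI in \[0, 1\].
#' @export
mean_hwi <- function(dyads, convention = c("printed", "standard")) {
  if (inherits(dyads, "association_summary")) dyads <- dyads$dyads
  if (!nrow(dyads)) stop("no co-available dyads to average over")
  if ("hwi" %in% names(dyads)) return(mean(dyads$hwi))
  mean(hwi(dyads$n_ab, dyads$n_a, dyads$n_b, dyads$y_ab, convention))
}

#' Square HWI matrix
#'
#' @param summary an `association_summary`.
#' @return symmetric numeric matrix keyed by individual ID (diagonal `NA`).
#' @export
hwi_matrix <- function(summary) {
  ids <- sort(unique(c(summary$dyads$id_a, summary$dyads$id_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(summary$dyads$id_a, summary$dyads$id_b)] <- summary$dyads$hwi
  m[cbind(summary$dyads$id_b, summary$dyads$id_a)] <- summary$dyads$hwi
  m
}

#' Restrict sightings to each individual's core range
#'
#' Keeps a sighting iff its coordinates fall inside *that individual's* own
#' level-contour cell set (ownership is per-individual: a location inside
#' another animal's core but outside one's own is dropped). Used to repeat
#' the full analysis within core (50% UD) home ranges.
#'
#' @param table a `sighting_table`.
#' @param uds named list of `ud` objects (names = individual IDs).
#' @param level contour level, default 0.5.
#' @return filtered `sighting_table`.
#' @export
restrict_to_core <- function(table, uds, level = 0.5) {
  if (level >= 1) {
    keep_ids <- table$id %in% names(uds)
    if (!all(keep_ids)) {
      warning("dropping records of ", length(unique(table$id[!keep_ids])),
              " individual(s) without a UD")
    }
    out <- table[keep_ids, , drop = FALSE]
  } else {
    members <- lapply(uds, function(u) ud_contour(u, level)$member)
    keep <- logical(nrow(table))
    no_ud <- setdiff(unique(table$id), names(uds))
    if (length(no_ud)) {
      warning("dropping records of ", length(no_ud),
              " individual(s) without a UD")
    }
    for (id in intersect(unique(table$id), names(uds))) {
      rows <- which(table$id == id)
      rc <- cell_of(uds[[id]]$grid, table$x[rows], table$y[rows])
      ok <- !is.na(rc[, "row"]) & !is.na(rc[, "col"])
      ok[ok] <- members[[id]][rc[ok, , drop = FALSE]]
      keep[rows] <- ok
    }
    out <- table[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out, period_index = attr(table, "period_index"),
            class = c("sighting_table", "data.frame"))
}
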