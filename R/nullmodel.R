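#' Survey effort polygon for one sampling period
#'
#' Buffered convex hull of a period's sighting locations plus (optionally)
#' the survey launch point. Used to restrict which individuals can be
#' rostered in a simulated period, and where their random positions may
#' fall, when the survey design does not cover the whole study site each
#' period. The area is exact for convex hulls: hull area + perimeter x
#' buffer + pi x buffer^2 (degenerate one- or two-point hulls give a disc or
#' stadium).
#'
#' @param points two-column matrix/data frame of the period's sighting
#'   coordinates (>= 1 row).
#' @param launch optional launch-point coordinates `c(x, y)`.
#' @param buffer buffer radius in metres.
#' @param period_id optional period identifier carried in the result.
#' @return object of class `effort_polygon`: list with `period`, `vertices`
#'   (hull vertices, may be 1 or 2 rows when degenerate), `buffer`,
#'   `area_m2`, `area_km2`.
#' @export
effort_polygon <- function(points, launch = NULL, buffer = 1000,
                           period_id = NULL) {
  xy <- if (is.data.frame(points)) cbind(points$x, points$y) else points
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  if (!is.null(launch)) xy <- rbind(xy, launch)
  xy <- unique(xy)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[h, , drop = FALSE]
  degenerate <- nrow(v) < 3L
  if (degenerate && nrow(xy) >= 2L) {
    # collinear points: keep the two extremes of the segment
    d <- as.matrix(stats::dist(xy))
    ext <- which(d == max(d), arr.ind = TRUE)[1L, ]
    v <- xy[ext, , drop = FALSE]
  }
  if (degenerate && buffer <= 0) {
    stop("degenerate geometry: fewer than 3 non-collinear points and no buffer")
  }
  area <- polygon_area(v) + polygon_perimeter(v) * buffer + pi * buffer^2
  structure(list(period = period_id, vertices = v, buffer = buffer,
                 area_m2 = area, area_km2 = area / 1e6),
            class = "effort_polygon")
}

#' @rdname effort_polygon
#' @param poly an `effort_polygon`.
#' @param x,y point coordinates (vectorized).
#' @return logical: is each point inside the buffered polygon?
#' @export
effort_contains <- function(poly, x, y) {
  dist_to_convex(poly$vertices, x, y) <= poly$buffer + 1e-9
}

#' Per-period effort polygons for a whole study
#'
#' @param table a `sighting_table`.
#' @param launch optional launch point `c(x, y)` shared by all periods.
#' @param buffer buffer radius in metres.
#' @return named list of `effort_polygon` (names = period index).
#' @export
effort_polygons <- function(table, launch = NULL, buffer = 1000) {
  sp <- split(table[, c("x", "y")], table$period_idx)
  lapply(stats::setNames(sp, names(sp)), function(d) {
    effort_polygon(d, launch = launch, buffer = buffer)
  })
}

# Logical vector over grid cells (column-major, matching as.vector(density))
# whose centres fall inside the buffered polygon.
cells_in_polygon <- function(grid, poly) {
  cc <- grid_centres(grid)
  px <- rep(cc$x, each = grid$ny)
  py <- rep(cc$y, times = grid$nx)
  effort_contains(poly, px, py)
}

#' Per-period roster size for the null model
#'
#' Fixed mode returns the configured constant (typically the observed mean
#' number of individuals sighted per period -- never a tuning knob, since
#' inflating rosters inflates co-sighting rates and breaks comparability of
#' random and observed HWIs). Density mode converts the period's effort area
#' to an expected count via a standard population density, clamped to
#' `[2, n_available]`.
#'
#' @param config a [study_config()].
#' @param n_available number of individuals whose availability window
#'   contains the period.
#' @param area_km2 effort-polygon area (density mode only).
#' @return integer roster size.
#' @export
roster_size <- function(config, n_available, area_km2 = NULL) {
  if (n_available < 1L) stop("no available individuals for this period")
  if (config$roster_mode == "fixed") {
    n <- config$n_roster
    if (is.null(n)) stop("fixed roster mode needs `n_roster`")
  } else {
    if (is.null(area_km2)) stop("density roster mode needs an effort polygon")
    n <- max(2, round(config$density * area_km2))
  }
  as.integer(min(n, n_available))
}

#' Sample a period's roster of individuals
#'
#' Samples `n` individuals without replacement from those whose availability
#' window contains the period, with inclusion weight proportional to each
#' individual's UD mass inside the period's effort polygon (uniform weights
#' when there is no effort geometry). Zero-weight individuals are never
#' sampled.
#'
#' @param ids character vector of available individuals.
#' @param n roster size.
#' @param weights non-negative inclusion weights (same length as `ids`);
#'   `NULL` for uniform.
#' @return character vector of sampled individuals.
#' @export
sample_roster <- function(ids, n, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(ids))
  pos <- weights > 0
  ids <- ids[pos]; weights <- weights[pos]
  n <- min(n, length(ids))
  if (n == 0L) return(character(0))
  if (n == length(ids)) return(ids)
  ids[sample.int(length(ids), n, prob = weights)]
}

#' Draw random positions from a utilization distribution
#'
#' Draws grid cells with probability proportional to UD mass (optionally
#' restricted and renormalized to the cells inside an effort polygon), then
#' jitters uniformly within each cell.
#'
#' @param ud a `ud` object.
#' @param n number of positions.
#' @param allowed optional logical vector over grid cells (column-major)
#'   restricting the support, e.g. from [cells_in_polygon()].
#' @return `n x 2` matrix of coordinates.
#' @export
sample_position <- function(ud, n = 1L, allowed = NULL) {
  d <- as.vector(ud$density)
  if (!is.null(allowed)) {
    d[!allowed] <- 0
    s <- sum(d)
    if (s <= 0) stop("individual has zero UD mass inside the effort polygon")
    d <- d / s
  }
  cells <- sample.int(length(d), n, replace = TRUE, prob = d)
  g <- ud$grid
  rows <- ((cells - 1L) %% g$ny) + 1L
  cols <- ((cells - 1L) %/% g$ny) + 1L
  cbind(x = g$x0 + (cols - 1L + stats::runif(n)) * g$cell,
        y = g$y0 + (rows - 1L + stats::runif(n)) * g$cell)
}

#' Default fixed roster size
#'
#' The observed mean number of individuals sighted per period, rounded --
#' the fixed-mode default. Roster size is never used to tune the null's
#' sociability (only the grouping distance is), so it always mirrors the
#' observed sampling intensity.
#'
#' @param table a `sighting_table`.
#' @return integer roster size.
#' @export
default_roster <- function(table) {
  as.integer(round(nrow(table) / length(unique(table$period_idx))))
}

# Precomputed state shared by all replicates of a null run.
null_state <- function(uds, availability, config, effort = NULL) {
  ids <- availability$id
  uds <- uds[ids]
  if (any(vapply(uds, is.null, logical(1L)))) {
    stop("every individual in `availability` needs a UD")
  }
  if (config$ud_level < 1) uds <- lapply(uds, restrict_ud, config$ud_level)
  n_obs_periods <- attr(availability, "n_periods")
  n_periods <- as.integer(config$n_periods %||% n_obs_periods)
  av <- availability
  if (n_periods != n_obs_periods) {
    # rescale windows proportionally onto the simulated period axis
    f <- n_periods / n_obs_periods
    av$first <- pmax(1L, as.integer(ceiling(av$first * f)))
    av$last <- pmin(n_periods, as.integer(ceiling(av$last * f)))
  }
  avail_by_period <- lapply(seq_len(n_periods), function(p) {
    which(av$first <= p & av$last >= p)
  })
  poly_cells <- NULL
  weights <- NULL
  areas <- NULL
  if (!is.null(effort)) {
    grid <- uds[[1L]]$grid
    poly_cells <- lapply(effort, function(pl) cells_in_polygon(grid, pl))
    areas <- vapply(effort, function(pl) pl$area_km2, numeric(1L))
    dens_mat <- vapply(uds, function(u) as.vector(u$density),
                       numeric(uds[[1L]]$grid$nx * uds[[1L]]$grid$ny))
    weights <- vapply(poly_cells, function(pc) colSums(dens_mat * pc),
                      numeric(length(ids)))  # n_ids x n_polys
    if (is.null(dim(weights))) weights <- matrix(weights, nrow = length(ids))
  }
  list(ids = ids, uds = uds, av = av, n_periods = n_periods,
       avail_by_period = avail_by_period, effort = effort,
       poly_cells = poly_cells, poly_weights = weights, poly_areas = areas,
       config = config)
}

# One replicate: returns list (names = period index) of list(ids, xy).
# RNG state is the caller's responsibility.
sim_replicate_core <- function(st) {
  cfg <- st$config
  fixed_n <- if (cfg$roster_mode == "fixed") {
    if (is.null(cfg$n_roster)) stop("fixed roster mode needs `n_roster`")
    cfg$n_roster
  } else NULL
  rostered <- vector("list", st$n_periods)
  for (p in seq_len(st$n_periods)) {
    avail <- st$avail_by_period[[p]]
    if (!length(avail)) next
    pkey <- as.character(p)
    has_poly <- !is.null(st$effort) && pkey %in% names(st$effort)
    w <- if (has_poly) st$poly_weights[avail, pkey] else NULL
    n <- if (!is.null(fixed_n)) min(fixed_n, length(avail)) else {
      roster_size(cfg, length(avail), st$poly_areas[[pkey]])
    }
    sel <- sample_roster(st$ids[avail], n, w)
    if (length(sel)) rostered[[p]] <- sel
  }
  out <- vector("list", st$n_periods)
  names(out) <- as.character(seq_len(st$n_periods))
  if (is.null(st$effort)) {
    # group draws by individual: one multinomial cell draw per individual
    all_ids <- unlist(rostered, use.names = FALSE)
    all_p <- rep(seq_len(st$n_periods),
                 vapply(rostered, length, integer(1L)))
    xy <- matrix(NA_real_, length(all_ids), 2L)
    for (id in unique(all_ids)) {
      take <- which(all_ids == id)
      xy[take, ] <- sample_position(st$uds[[id]], length(take))
    }
    for (p in which(lengths(rostered) > 0L)) {
      take <- which(all_p == p)
      out[[p]] <- list(ids = all_ids[take], xy = xy[take, , drop = FALSE])
    }
  } else {
    for (p in which(lengths(rostered) > 0L)) {
      sel <- rostered[[p]]
      pkey <- as.character(p)
      allowed <- if (pkey %in% names(st$effort)) st$poly_cells[[pkey]] else NULL
      xy <- matrix(NA_real_, length(sel), 2L)
      for (k in seq_along(sel)) {
        xy[k, ] <- sample_position(st$uds[[sel[k]]], 1L, allowed)
      }
      out[[p]] <- list(ids = sel, xy = xy)
    }
  }
  out[!vapply(out, is.null, logical(1L))]
}

period_list_to_table <- function(period_list, period_index = NULL) {
  rows <- lapply(names(period_list), function(pname) {
    rec <- period_list[[pname]]
    data.frame(id = rec$ids, period = as.integer(pname),
               x = rec$xy[, 1L], y = rec$xy[, 2L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(period_index)) df$period <- period_index[df$period]
  as_sighting_table(df, period_index = period_index %||%
                      seq_len(max(df$period)))
}

#' Simulate one replicate dataset under the null model
#'
#' Places every rostered individual at a random position drawn from its UD
#' (restricted to the period's effort polygon when one exists), for every
#' sampling period, honouring temporal availability. The output has the
#' same period structure as the observed data, so observed and simulated
#' tables are tallied identically.
#'
#' @param uds named list of `ud` objects.
#' @param availability availability windows from [derive_availability()].
#' @param config a [study_config()].
#' @param seed RNG seed for this replicate.
#' @param effort optional named list of `effort_polygon` (names = period
#'   index), see [effort_polygons()].
#' @return a `sighting_table` of simulated sightings.
#' @export
simulate_replicate <- function(uds, availability, config, seed,
                               effort = NULL) {
  st <- null_state(uds, availability, config, effort)
  set.seed(seed)
  period_list_to_table(sim_replicate_core(st))
}

#' Per-dyad null distributions of the half-weight index
#'
#' Runs `B` independent replicates of the null model (each with its own
#' deterministic child seed), tallies dyadic associations at the null
#' grouping distance `gprox`, and assembles each dyad's array of `B` random
#' HWIs over the same dyad universe as the observed analysis (pairs with
#' non-empty joint availability).
#'
#' @inheritParams simulate_replicate
#' @param gprox null-model grouping distance in metres (typically the value
#'   selected by [select_gprox()]).
#' @param B number of replicates.
#' @param seed master seed; child seeds are derived per replicate so results
#'   are reproducible and replicate-order independent.
#' @return object of class `null_distribution`: list with `dyads` (the dyad
#'   universe), `hwi` (matrix, dyads x B), `gprox`, `seeds`.
#' @export
null_distributions <- function(uds, availability, config, gprox,
                               B = config$B, seed = config$seed,
                               effort = NULL) {
  st <- null_state(uds, availability, config, effort)
  dyads <- dyad_universe(st$av)
  seeds <- child_seeds(seed, B)
  H <- matrix(NA_real_, nrow(dyads), B)
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    pl <- sim_replicate_core(st)
    tal <- tally_core(pl, st$av, st$n_periods, gprox, config$grouping_mode,
                      dyads = dyads)
    H[, b] <- hwi(tal$n_ab, tal$n_a, tal$n_b, tal$y_ab, config$hwi_convention)
  }
  structure(list(dyads = dyads, hwi = H, gprox = gprox, seeds = seeds,
                 convention = config$hwi_convention),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", nrow(x$dyads), " dyads x ", ncol(x$hwi),
      " replicates, gprox ", x$gprox, " m, mean random HWI ",
      signif(mean(x$hwi), 4), "\n", sep = "")
  invisible(x)
}
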