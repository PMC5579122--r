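#' Construct an analysis grid
#'
#' All utilization distributions (UDs) in a study share one grid so that
#' overlap indices and the null model's position sampling are defined
#' cell-by-cell. An optional boundary mask (e.g. land for a marine study)
#' marks the cells that belong to the study area; masked-out cells always
#' carry zero probability mass.
#'
#' @param xlim,ylim numeric length-2 extents in metres.
#' @param cell cell size in metres (> 0). Choose `cell <= bandwidth / 2` so
#'   the kernel is resolved by the grid.
#' @param mask optional logical matrix (`nrow = n_rows`, `ncol = n_cols`,
#'   rows indexing y, columns indexing x) with `TRUE` for cells inside the
#'   study boundary.
#' @return an object of class `ud_grid`.
#' @export
make_grid <- function(xlim, ylim, cell, mask = NULL) {
  stopifnot(cell > 0, xlim[2] > xlim[1], ylim[2] > ylim[1])
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / cell))
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / cell))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), nrow(mask) == ny, ncol(mask) == nx)
    if (!any(mask)) stop("boundary mask excludes every cell")
  }
  structure(list(x0 = xlim[1], y0 = ylim[1], cell = cell,
                 nx = nx, ny = ny, mask = mask),
            class = "ud_grid")
}

#' @rdname make_grid
#' @param table a `sighting_table` (or two-column coordinate matrix).
#' @param pad margin added around the data extent, in metres; defaults to
#'   three bandwidths' worth of space when `bandwidth` is supplied.
#' @param bandwidth optional bandwidth used to choose the default padding.
#' @export
grid_from_points <- function(table, cell, pad = NULL, bandwidth = NULL,
                             mask = NULL) {
  xy <- if (is.data.frame(table)) cbind(table$x, table$y) else table
  if (is.null(pad)) pad <- if (is.null(bandwidth)) 3 * cell else 3 * bandwidth
  make_grid(range(xy[, 1]) + c(-pad, pad), range(xy[, 2]) + c(-pad, pad),
            cell, mask = mask)
}

grid_centres <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell,
       y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$x0, b$x0)) && isTRUE(all.equal(a$y0, b$y0)) &&
    isTRUE(all.equal(a$cell, b$cell)) && a$nx == b$nx && a$ny == b$ny
}

# Row/col of the cell containing each point; NA when off-grid.
cell_of <- function(grid, x, y) {
  col <- ceiling((x - grid$x0) / grid$cell)
  row <- ceiling((y - grid$y0) / grid$cell)
  col[col < 1L | col > grid$nx] <- NA_integer_
  row[row < 1L | row > grid$ny] <- NA_integer_
  # points exactly on the lower/left boundary fall in the first cell
  col[!is.na(col) & col == 0L] <- 1L
  row[!is.na(row) & row == 0L] <- 1L
  cbind(row = row, col = col)
}

#' Reference bandwidth for kernel home-range estimation
#'
#' The standard bivariate-normal reference ("href") bandwidth,
#' \eqn{h = 0.5 (s_x + s_y) n^{-1/6}}, where \eqn{s_x, s_y} are the marginal
#' standard deviations of the relocations. Used for individual-specific
#' smoothing when no externally optimized bandwidth is available.
#'
#' @param points two-column matrix or data frame of coordinates (>= 5 rows).
#' @return bandwidth in metres (strictly positive).
#' @export
reference_bandwidth <- function(points) {
  xy <- if (is.data.frame(points)) cbind(points$x, points$y) else points
  n <- nrow(xy)
  if (n < 5L) stop("reference bandwidth needs at least 5 points")
  h <- 0.5 * (stats::sd(xy[, 1]) + stats::sd(xy[, 2])) * n^(-1 / 6)
  if (!is.finite(h) || h <= 0) {
    stop("degenerate point spread: all coordinates identical")
  }
  h
}

#' Estimate a gridded kernel utilization distribution
#'
#' Isotropic bivariate Gaussian kernel density, evaluated at cell centres,
#' multiplied by cell area, clipped to the boundary mask, then renormalized
#' so the per-cell probability masses total 1. The result is the discrete UD
#' used by every downstream operation (contours, overlap, null sampling).
#'
#' @param points two-column matrix or data frame of relocations (>= 1 row).
#' @param bandwidth kernel standard deviation in metres (> 0).
#' @param grid a [make_grid()] object.
#' @param id optional individual identifier carried in the result.
#' @return object of class `ud`: list with `id`, `grid`, `density` (a
#'   `ny x nx` matrix of cell probability masses summing to 1) and
#'   `bandwidth`.
#' @export
estimate_ud <- function(points, bandwidth, grid, id = NULL) {
  xy <- if (is.data.frame(points)) cbind(points$x, points$y) else points
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  stopifnot(nrow(xy) >= 1L, bandwidth > 0)
  cc <- grid_centres(grid)
  kx <- stats::dnorm(outer(cc$x, xy[, 1], "-"), sd = bandwidth)  # nx x n
  ky <- stats::dnorm(outer(cc$y, xy[, 2], "-"), sd = bandwidth)  # ny x n
  dens <- (ky %*% t(kx)) / nrow(xy) * grid$cell^2
  if (!is.null(grid$mask)) dens[!grid$mask] <- 0
  tot <- sum(dens)
  if (tot <= 0) stop("all kernel mass falls outside the masked grid")
  structure(list(id = id, grid = grid, density = dens / tot,
                 bandwidth = bandwidth),
            class = "ud")
}

#' @export
print.ud <- function(x, ...) {
  cat("<ud> ", x$id %||% "(unnamed)", ": ", x$grid$ny, "x", x$grid$nx,
      " grid, cell ", x$grid$cell, " m, bandwidth ", signif(x$bandwidth, 4),
      " m\n", sep = "")
  invisible(x)
}

#' Raster home-range contour of a utilization distribution
#'
#' The smallest set of cells, taken in decreasing density order, whose
#' cumulative probability mass reaches `level`. `level = 1` returns the full
#' positive-mass support. Contours are raster cell sets (not vectorized
#' isopleths); the area is cell count times cell area.
#'
#' @param ud a [estimate_ud()] object.
#' @param level contour level in (0, 1]; 0.95 gives the conventional "full"
#'   home range, 0.50 the core range.
#' @return object of class `ud_contour`: list with `id`, `level`, `cells`
#'   (linear indices into the density matrix), `member` (logical matrix),
#'   `area` (m^2), `centroid` (x, y) and `grid`.
#' @export
ud_contour <- function(ud, level) {
  stopifnot(level > 0, level <= 1)
  d <- as.vector(ud$density)
  pos <- which(d > 0)
  ord <- pos[order(d[pos], decreasing = TRUE)]
  if (level >= 1) {
    cells <- ord
  } else {
    k <- which(cumsum(d[ord]) >= level - 1e-12)[1L]
    cells <- ord[seq_len(k)]
  }
  member <- matrix(FALSE, ud$grid$ny, ud$grid$nx)
  member[cells] <- TRUE
  cc <- grid_centres(ud$grid)
  rows <- ((cells - 1L) %% ud$grid$ny) + 1L
  cols <- ((cells - 1L) %/% ud$grid$ny) + 1L
  structure(list(id = ud$id, level = level, cells = cells, member = member,
                 area = length(cells) * ud$grid$cell^2,
                 centroid = c(x = mean(cc$x[cols]), y = mean(cc$y[rows])),
                 grid = ud$grid),
            class = "ud_contour")
}

#' Volume of intersection between two utilization distributions
#'
#' Overlap index \eqn{VI = \sum_{cells} \min(p_a, p_b)} between two UDs on
#' the same grid: 0 for disjoint space use, 1 for identical UDs.
#'
#' @param ud_a,ud_b `ud` objects on the same grid.
#' @return VI in \[0, 1\].
#' @export
volume_intersection <- function(ud_a, ud_b) {
  if (!same_grid(ud_a$grid, ud_b$grid)) stop("UDs are on different grids")
  sum(pmin(ud_a$density, ud_b$density))
}

#' @rdname volume_intersection
#' @param level restrict both UDs to their own `level` contour and
#'   renormalize before computing VI (e.g. 0.95 or 0.50 overlap).
#' @export
vi_at_level <- function(ud_a, ud_b, level = 0.95) {
  volume_intersection(restrict_ud(ud_a, level), restrict_ud(ud_b, level))
}

# UD conditioned on its own level-contour (zero outside, renormalized).
restrict_ud <- function(ud, level) {
  if (level >= 1) return(ud)
  ct <- ud_contour(ud, level)
  d <- ud$density
  d[!ct$member] <- 0
  ud$density <- d / sum(d)
  ud
}

#' Minimum centroid-to-contour distance
#'
#' The minimum distance from a contour region's centroid to its boundary
#' cells (region cells adjacent to a non-region cell or the grid edge). The
#' population minimum of this quantity bounds the admissible grouping
#' distances tested during null-model calibration, keeping them biologically
#' possible.
#'
#' @param ud a `ud` object.
#' @param level contour level, default 0.95.
#' @return distance in metres; half a cell size for a single-cell region.
#' @export
centroid_contour_distance <- function(ud, level = 0.95) {
  ct <- ud_contour(ud, level)
  m <- ct$member
  if (sum(m) == 1L) return(ud$grid$cell / 2)
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  interior <- pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  boundary <- which(m & !interior)
  cc <- grid_centres(ud$grid)
  rows <- ((boundary - 1L) %% ny) + 1L
  cols <- ((boundary - 1L) %/% ny) + 1L
  min(sqrt((cc$x[cols] - ct$centroid["x"])^2 +
           (cc$y[rows] - ct$centroid["y"])^2))
}

#' Home-range stabilization diagnostic
#'
#' Re-estimates each individual's UD from random subsamples of increasing
#' size and tracks the mean 95%-contour area (and, optionally, the
#' correlation of pairwise VI overlap with the full-data VI). The sample size
#' at which the area curve plateaus is the minimum number of sightings needed
#' for stable home-range estimates; the choice of threshold is made by
#' inspecting the curve.
#'
#' @param table a `sighting_table`.
#' @param n_values increasing sighting counts to evaluate.
#' @param reps random subsamples per count.
#' @param seed RNG seed.
#' @param bandwidth fixed bandwidth in metres, or `"href"` for the
#'   per-individual, per-subsample reference bandwidth.
#' @param cell grid cell size in metres.
#' @param level contour level for the area (default 0.95).
#' @param vi also track the correlation between subsample pairwise VI and
#'   full-data pairwise VI (needs >= 3 individuals).
#' @return data frame of class `stabilization_curve` with columns `n`,
#'   `mean_area`, `sd_area` (m^2) and, when `vi = TRUE`, `mean_vi_cor`,
#'   `sd_vi_cor`.
#' @export
stabilization_curve <- function(table, n_values, reps = 10, seed = 1,
                                bandwidth = "href", cell, level = 0.95,
                                vi = FALSE) {
  counts <- sighting_counts(table)
  bw_ref <- if (identical(bandwidth, "href")) {
    max(vapply(split(table, table$id),
               function(d) reference_bandwidth(d), numeric(1L)))
  } else bandwidth
  grid <- grid_from_points(table, cell = cell, bandwidth = bw_ref)
  by_id <- split(table[, c("x", "y")], table$id)
  ud_of <- function(xy) {
    h <- if (identical(bandwidth, "href")) reference_bandwidth(xy) else bandwidth
    estimate_ud(xy, h, grid)
  }
  full_vi <- NULL
  if (vi) {
    uds <- lapply(by_id, ud_of)
    full_vi <- pairwise_vi(uds)
  }
  set.seed(seed)
  out <- lapply(sort(n_values), function(n) {
    usable <- names(counts)[counts >= n]
    skipped <- setdiff(names(counts), usable)
    if (length(skipped)) {
      warning("skipping ", length(skipped),
              " individual(s) with fewer than ", n, " sightings")
    }
    if (!length(usable)) return(NULL)
    areas <- numeric(reps)
    vic <- numeric(reps)
    for (r in seq_len(reps)) {
      uds_r <- lapply(by_id[usable], function(xy) {
        ud_of(xy[sample.int(nrow(xy), n), , drop = FALSE])
      })
      areas[r] <- mean(vapply(uds_r, function(u) ud_contour(u, level)$area,
                              numeric(1L)))
      if (vi && length(usable) >= 3L) {
        sub_vi <- pairwise_vi(uds_r)
        vic[r] <- stats::cor(sub_vi, full_vi[names(sub_vi)])
      }
    }
    row <- data.frame(n = n, mean_area = mean(areas), sd_area = stats::sd(areas))
    if (vi) {
      row$mean_vi_cor <- mean(vic)
      row$sd_vi_cor <- stats::sd(vic)
    }
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("stabilization_curve", "data.frame")
  out
}

pairwise_vi <- function(uds) {
  ids <- sort(names(uds))
  cmb <- utils::combn(ids, 2L)
  v <- vapply(seq_len(ncol(cmb)),
              function(k) volume_intersection(uds[[cmb[1L, k]]], uds[[cmb[2L, k]]]),
              numeric(1L))
  names(v) <- paste(cmb[1L, ], cmb[2L, ], sep = "|")
  v
}

#' Export a utilization distribution as an ESRI ASCII raster
#'
#' Plain-text grid export (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA
#' header followed by rows from the top of the grid down), readable by
#' standard GIS tools.
#'
#' @param ud a `ud` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_ud_ascii <- function(ud, path) {
  g <- ud$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$nx), paste("nrows", g$ny),
    paste("xllcorner", g$x0), paste("yllcorner", g$y0),
    paste("cellsize", g$cell), "NODATA_value -9999"), con)
  for (r in rev(seq_len(g$ny))) {
    writeLines(paste(format(ud$density[r, ], scientific = TRUE), collapse = " "),
               con)
  }
  invisible(path)
}

#' Export a contour region as GeoJSON
#'
#' Writes the contour's member cells as a GeoJSON MultiPolygon of cell
#' squares, for quick visualization in GIS or web tools.
#'
#' @param contour a `ud_contour` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_contour_geojson <- function(contour, path) {
  g <- contour$grid
  rows <- ((contour$cells - 1L) %% g$ny) + 1L
  cols <- ((contour$cells - 1L) %/% g$ny) + 1L
  polys <- vapply(seq_along(rows), function(k) {
    x0 <- g$x0 + (cols[k] - 1L) * g$cell
    y0 <- g$y0 + (rows[k] - 1L) * g$cell
    x1 <- x0 + g$cell; y1 <- y0 + g$cell
    sprintf("[[[%g,%g],[%g,%g],[%g,%g],[%g,%g],[%g,%g]]]",
            x0, y0, x1, y0, x1, y1, x0, y1, x0, y0)
  }, character(1L))
  json <- paste0(
    '{"type":"Feature","properties":{"id":"', contour$id %||% "",
    '","level":', contour$level, '},"geometry":{"type":"MultiPolygon",',
    '"coordinates":[', paste(polys, collapse = ","), "]}}")
  writeLines(json, path)
  invisible(path)
}
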