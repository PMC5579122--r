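#' Build a sighting table from a data frame
#'
#' A sighting table is the central input container: one row per individual per
#' sampling period, with planar metric coordinates. Within-period duplicates
#' are resolved by keeping the *last* row for that individual and period
#' (matching the convention of using the last survey of the day), so each
#' individual contributes at most one record per period.
#'
#' @param df data frame with at least columns `id`, `period`, `x`, `y`.
#'   Additional columns (e.g. `sex`, an aggression flag) are carried through
#'   untouched.
#' @param period_index optional ordered vector of all surveyed period labels;
#'   defaults to the sorted unique periods present in `df`. Supply a superset
#'   when some surveys produced no usable sightings.
#' @return an object of class `sighting_table`: a data frame with the input
#'   columns plus `period_idx` (integer position of the period in the study's
#'   ordered period index), and attributes `period_index`.
#' @details Coordinates must be planar and in metres (a projected CRS);
#'   geographic longitude/latitude is rejected because all distance
#'   parameters (grouping distances, bandwidths, buffers) are metric.
#' @seealso [read_sightings()], [derive_availability()], [filter_min_sightings()]
#' @export
as_sighting_table <- function(df, period_index = NULL) {
  req <- c("id", "period", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("sighting table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  ok <- is.finite(df$x) & is.finite(df$y)
  if (any(!ok)) {
    message("dropping ", sum(!ok), " row(s) with missing or non-finite coordinates")
    df <- df[ok, , drop = FALSE]
  }
  if (!nrow(df)) stop("no valid sighting records")
  if (looks_geographic(df$x, df$y)) {
    stop("coordinates look like longitude/latitude; project to planar metres first")
  }
  if (is.null(period_index)) {
    period_index <- order_periods(unique(df$period))
  } else {
    period_index <- order_periods(unique(period_index))
    if (!all(df$period %in% period_index)) {
      stop("some records have periods absent from `period_index`")
    }
  }
  df$period_idx <- match(df$period, period_index)
  # keep the LAST row per (individual, period)
  keep <- !duplicated(df[, c("id", "period_idx")], fromLast = TRUE)
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$period_idx, df$id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            period_index = period_index,
            class = c("sighting_table", "data.frame"))
}

# Conservative heuristic: fractional-degree-sized coordinates. Metric test
# fixtures with small integer coordinates are deliberately not flagged.
looks_geographic <- function(x, y) {
  all(abs(x) <= 180) && all(abs(y) <= 90) &&
    diff(range(x)) < 1 && diff(range(y)) < 1 &&
    any(x %% 1 != 0 | y %% 1 != 0)
}

order_periods <- function(p) {
  num <- suppressWarnings(as.numeric(p))
  if (!anyNA(num)) return(p[order(num)])
  d <- suppressWarnings(as.Date(as.character(p)))
  if (!anyNA(d)) return(p[order(d)])
  sort(p)
}

#' @export
print.sighting_table <- function(x, ...) {
  cat("<sighting_table> ", nrow(x), " records, ",
      length(unique(x$id)), " individuals, ",
      length(attr(x, "period_index")), " periods\n", sep = "")
  invisible(x)
}

#' Read a sighting table from a delimited text file
#'
#' Reads a CSV/TSV of longitudinal sighting records, applies column mapping,
#' drops rows with missing or non-finite coordinates (with a message), and
#' deduplicates to one record per individual per period, keeping the last row.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping the required names
#'   (`id`, `period`, `x`, `y`) to the column names in the file. Unmapped
#'   columns are carried through under their original names.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param period_index optional ordered vector of all surveyed periods.
#' @return a [as_sighting_table()] object.
#' @export
read_sightings <- function(path,
                           column_map = c(id = "id", period = "period",
                                          x = "x", y = "y"),
                           sep = NULL, period_index = NULL) {
  if (!file.exists(path)) stop("sightings file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("empty sightings file: ", path)
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("sightings file has a header but no data rows: ", path)
  req <- c("id", "period", "x", "y")
  cm <- column_map[req]
  if (anyNA(cm) || !all(cm %in% names(df))) {
    stop("column_map does not resolve required columns (id, period, x, y) ",
         "against file columns: ", paste(names(df), collapse = ", "))
  }
  names(df)[match(cm, names(df))] <- req
  as_sighting_table(df, period_index = period_index)
}

#' Per-individual sighting counts
#'
#' @param table a `sighting_table`.
#' @return named integer vector: number of distinct periods in which each
#'   individual was sighted.
#' @export
sighting_counts <- function(table) {
  tab <- table(table$id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Derive temporal availability windows
#'
#' An individual's availability window spans its first to last sighted period
#' (inclusive), a conservative stand-in for entry/exit dates in populations
#' with demographic turnover. Dyadic analyses are restricted to the overlap of
#' the two members' windows, and the null model never places an individual in
#' a period outside its window.
#'
#' @param table a `sighting_table`.
#' @return data frame with columns `id`, `first`, `last` (integer period
#'   indices, inclusive), one row per individual.
#' @export
derive_availability <- function(table) {
  if (!nrow(table)) stop("empty sighting table")
  sp <- split(table$period_idx, table$id)
  out <- data.frame(
    id = names(sp),
    first = vapply(sp, min, integer(1L)),
    last = vapply(sp, max, integer(1L)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_periods") <- length(attr(table, "period_index"))
  out
}

#' Filter a sighting table to well-sampled individuals
#'
#' Retains exactly the individuals with at least `n_min` sightings. The
#' period index is unchanged, so period positions (and hence availability
#' windows) keep their meaning.
#'
#' @param table a `sighting_table`.
#' @param n_min minimum number of sightings (>= 1).
#' @return a filtered `sighting_table`.
#' @export
filter_min_sightings <- function(table, n_min) {
  stopifnot(n_min >= 1)
  counts <- sighting_counts(table)
  keep <- names(counts)[counts >= n_min]
  if (!length(keep)) {
    warning("no individual has >= ", n_min, " sightings; result is empty")
  }
  out <- table[table$id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            period_index = attr(table, "period_index"),
            class = c("sighting_table", "data.frame"))
}

#' Write and read dyadic result tables
#'
#' Serializes dyadic results as plain CSV, one row per dyad; the
#' `read_dyad_results()` counterpart restores the same field values, so the
#' pair round-trips losslessly.
#'
#' @param results a data frame of dyadic results (see [run_inference()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dyad_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_dyad_results
#' @export
read_dyad_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
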