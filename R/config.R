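#' Study configuration
#'
#' Collects every tunable parameter of an avoidance analysis in one object.
#' Defaults follow the full-coverage terrestrial parameterization (B = 1000
#' replicates, alpha = 0.05, pairwise grouping, fixed per-period roster);
#' marine-style designs switch on effort geometry and density-based rosters.
#'
#' @param gprox_observed distance proxy (m) defining association in the
#'   observed data; must be > 0.
#' @param cell_size UD grid cell size (m). Also the default increment of the
#'   calibration sweep. Choose `cell_size <= bandwidth / 2`.
#' @param bandwidth kernel bandwidth (m), or `"href"` for per-individual
#'   reference bandwidths.
#' @param grouping_mode `"pairwise"` or `"chain"`.
#' @param min_sightings_ud minimum sightings for a stable UD (individuals
#'   below it are excluded before home-range estimation).
#' @param min_sightings_classify minimum sightings to classify a dyad's
#'   relationship post hoc (applied after the null model is built).
#' @param B number of null-model replicates.
#' @param alpha tail probability for classification, in (0, 0.5].
#' @param ud_level 1.0 for the full home range, 0.5 for a core-range run.
#' @param seed master RNG seed.
#' @param roster_mode `"fixed"` (constant per-period roster) or
#'   `"density"` (roster from population density times effort-polygon area).
#' @param n_roster fixed-mode roster size; `NULL` means the observed mean
#'   number of individuals per period.
#' @param density population density (individuals per km^2), density mode.
#' @param effort_buffer buffer (m) around daily survey hulls.
#' @param n_periods number of random sampling periods; `NULL` means the
#'   observed number of periods.
#' @param hwi_convention `"printed"` or `"standard"`, see [hwi()].
#' @param sweep_reps replicates per candidate during the calibration sweep
#'   (the final null run uses the full `B`).
#' @param candidates candidate gprox values for the sweep; `NULL` means
#'   multiples of `cell_size` up to the admissible bound.
#' @param gprox_null fixed null grouping distance; non-`NULL` skips the
#'   calibration sweep.
#' @return object of class `study_config` (a validated list).
#' @export
study_config <- function(gprox_observed,
                         cell_size,
                         bandwidth = "href",
                         grouping_mode = c("pairwise", "chain"),
                         min_sightings_ud = 25,
                         min_sightings_classify = min_sightings_ud,
                         B = 1000,
                         alpha = 0.05,
                         ud_level = 1.0,
                         seed = 1,
                         roster_mode = c("fixed", "density"),
                         n_roster = NULL,
                         density = NULL,
                         effort_buffer = 1000,
                         n_periods = NULL,
                         hwi_convention = c("printed", "standard"),
                         sweep_reps = 100,
                         candidates = NULL,
                         gprox_null = NULL) {
  cfg <- list(
    gprox_observed = gprox_observed,
    cell_size = cell_size,
    bandwidth = bandwidth,
    grouping_mode = match.arg(grouping_mode),
    min_sightings_ud = min_sightings_ud,
    min_sightings_classify = min_sightings_classify,
    B = as.integer(B),
    alpha = alpha,
    ud_level = ud_level,
    seed = seed,
    roster_mode = match.arg(roster_mode),
    n_roster = n_roster,
    density = density,
    effort_buffer = effort_buffer,
    n_periods = n_periods,
    hwi_convention = match.arg(hwi_convention),
    sweep_reps = as.integer(sweep_reps),
    candidates = candidates,
    gprox_null = gprox_null
  )
  stopifnot(cfg$gprox_observed > 0, cfg$B >= 1L,
            cfg$alpha > 0, cfg$alpha <= 0.5,
            cfg$cell_size > 0, cfg$ud_level %in% c(0.5, 1.0))
  if (cfg$roster_mode == "density" && is.null(cfg$density)) {
    stop("density roster mode needs `density` (individuals per km^2)")
  }
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "(auto)" else paste(format(v), collapse = " ")))
  }
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Parses lines of the form `key: value` or `key = value` (blank lines and
#' `#` comments ignored), coerces numeric and logical values, and builds a
#' [study_config()]. Keys not belonging to the configuration (e.g. `input`,
#' `out_dir`, `launch_x`) are returned in the `extra` attribute.
#'
#' @param path path to the configuration file.
#' @return a `study_config` with attribute `extra`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- lapply(lines, function(l) {
    m <- regmatches(l, regexec("^([^:=]+)[:=](.*)$", l))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", l)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (val %in% c("TRUE", "true", "FALSE", "false")) {
      val <- as.logical(toupper(val))
    }
    stats::setNames(list(val), trimws(m[2]))
  })
  kv <- do.call(c, kv)
  known <- names(formals(study_config))
  cfg <- do.call(study_config, kv[intersect(names(kv), known)])
  attr(cfg, "extra") <- kv[setdiff(names(kv), known)]
  cfg
}
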