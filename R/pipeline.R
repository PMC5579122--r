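#' Run the full avoidance analysis end-to-end
#'
#' Executes the complete workflow: ingest -> minimum-sightings filter for
#' home-range estimation -> UD estimation -> observed association tally ->
#' admissible-bound check -> calibration sweep and gprox selection ->
#' B-replicate null model -> post-hoc classification filter -> per-dyad
#' p-values, classification and overlap-based avoidance strength. With
#' `config$ud_level = 0.5` the whole chain runs on the core-range
#' restriction: observed sightings are clipped to each individual's 50% UD
#' and the null samples from UDs renormalized within the same region, so
#' observed and null share one spatial domain.
#'
#' @param table a `sighting_table`, or a path to a sightings file.
#' @param config a [study_config()] (or a path to a config file for
#'   [read_config()]).
#' @param effort optional named list of `effort_polygon`s, or `TRUE` to
#'   build daily buffered hulls from the data (`launch` optional).
#' @param launch optional launch point `c(x, y)` used when building effort
#'   polygons.
#' @param out_dir optional directory: writes `dyad_results.csv`,
#'   `sweep.csv` and `manifest.txt`.
#' @return list of class `avoidance_run` with elements `results` (a
#'   `dyad_results` data frame ordered by avoidance strength), `sweep`,
#'   `gprox_selected`, `uds`, `observed`, `null`, and `manifest` (config
#'   echo, seed, stage counts, timings).
#' @export
run_full_analysis <- function(table, config, effort = NULL, launch = NULL,
                              out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(config)) config <- read_config(config)
  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = character(0), counts = list(), timings = list())
  stage <- function(name, expr) {
    tic <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - tic, 3)
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  tbl <- stage("ingest", {
    if (is.character(table)) read_sightings(table) else table
  })
  manifest$counts$n_records <- nrow(tbl)
  manifest$counts$n_individuals <- length(unique(tbl$id))

  tbl_ud <- stage("ud_filter", filter_min_sightings(tbl, config$min_sightings_ud))
  manifest$counts$n_individuals_ud <- length(unique(tbl_ud$id))

  uds <- stage("ud_estimation", estimate_uds(tbl_ud, config))

  if (isTRUE(effort)) {
    effort <- stage("effort", effort_polygons(tbl_ud, launch = launch,
                                              buffer = config$effort_buffer))
  } else if (isFALSE(effort)) {
    effort <- NULL
  }

  obs_tbl <- tbl_ud
  if (config$ud_level < 1) {
    obs_tbl <- stage("core_restriction",
                     restrict_to_core(tbl_ud, uds, config$ud_level))
    manifest$counts$n_records_core <- nrow(obs_tbl)
  }
  availability <- stage("availability", derive_availability(obs_tbl))
  observed <- stage("observed_associations",
                    association_summary(obs_tbl, config$gprox_observed,
                                        config$grouping_mode, availability,
                                        config$hwi_convention))
  manifest$counts$n_dyads_co_available <- nrow(observed$dyads)
  manifest$counts$observed_mean_hwi <- observed$mean_hwi

  if (config$roster_mode == "fixed" && is.null(config$n_roster)) {
    config$n_roster <- default_roster(obs_tbl)
    manifest$counts$n_roster <- config$n_roster
  }

  uds_run <- uds[intersect(names(uds), availability$id)]
  sweep <- NULL
  gprox_sel <- config$gprox_null
  if (is.null(gprox_sel)) {
    bound <- stage("admissible_bound", admissible_gprox_bound(uds_run))
    manifest$counts$gprox_bound <- bound
    sweep <- stage("gprox_sweep",
                   sweep_gprox(uds_run, availability, config,
                               candidates = config$candidates,
                               observed_mean_hwi = observed$mean_hwi,
                               effort = effort, bound = bound))
    gprox_sel <- stage("gprox_selection", select_gprox(sweep))
  }
  manifest$counts$gprox_selected <- gprox_sel

  nul <- stage("null_model",
               null_distributions(uds_run, availability, config, gprox_sel,
                                  B = config$B, seed = config$seed,
                                  effort = effort))
  results <- stage("inference",
                   run_inference(observed, nul, config$min_sightings_classify,
                                 config$alpha, uds = uds_run))
  results <- stage("strength", avoidance_strength(results))
  manifest$counts$n_dyads_classified <- nrow(results)
  manifest$counts$n_avoidance <- sum(results$classification == "avoidance")
  manifest$counts$n_preference <- sum(results$classification == "preference")
  manifest$timings$total <- round(proc.time()[["elapsed"]] - t0, 3)
  class(manifest) <- "run_manifest"

  out <- structure(list(results = results, sweep = sweep,
                        gprox_selected = gprox_sel, uds = uds_run,
                        observed = observed, null = nul,
                        manifest = manifest),
                   class = "avoidance_run")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_dyad_results(results, file.path(out_dir, "dyad_results.csv"))
    if (!is.null(sweep)) {
      utils::write.csv(as.data.frame(sweep), file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
    }
    writeLines(format_manifest(manifest), file.path(out_dir, "manifest.txt"))
  }
  out
}

format_manifest <- function(m) {
  cfg <- vapply(names(m$config), function(k) {
    v <- m$config[[k]]
    paste0("config.", k, ": ",
           if (is.null(v)) "(auto)" else paste(format(v), collapse = " "))
  }, character(1L))
  cnt <- vapply(names(m$counts), function(k) {
    paste0("count.", k, ": ", format(m$counts[[k]]))
  }, character(1L))
  tim <- vapply(names(m$timings), function(k) {
    paste0("time.", k, ": ", m$timings[[k]], "s")
  }, character(1L))
  c(cfg, cnt, tim)
}

#' @export
print.run_manifest <- function(x, ...) {
  writeLines(format_manifest(x))
  invisible(x)
}

#' @export
print.avoidance_run <- function(x, ...) {
  cat("<avoidance_run> gprox ", x$gprox_selected, " m, ",
      nrow(x$results), " classified dyads: ",
      x$manifest$counts$n_avoidance, " avoidance, ",
      x$manifest$counts$n_preference, " preference\n", sep = "")
  invisible(x)
}
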