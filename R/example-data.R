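#' Example calibration sweep tables
#'
#' Worked calibration examples from two longitudinal field studies: an
#' urban population of Eastern water dragons surveyed on a fully covered
#' transect (candidate grouping distances 1-9 m, in 1 m grid-cell
#' increments) and a bottlenose dolphin population surveyed by boat over a
#' large marine study site (candidates 600-1400 m, in 100 m increments).
#' Each table pairs the candidate null grouping distance with the mean
#' random half-weight index it produced, for the full home range and for
#' the 50% core range, together with the observed population mean HWI the
#' null is matched against.
#'
#' These tables make the selection rule concrete: [select_gprox()] picks
#' 5 m (dragons, full), 4 m (dragons, core), 1000 m (dolphins, full) and
#' 1100 m (dolphins, core).
#'
#' @return named list of four [sweep_table()] objects: `dragons_full`,
#'   `dragons_core`, `dolphins_full`, `dolphins_core`.
#' @examples
#' sw <- example_sweeps()
#' select_gprox(sw$dolphins_full)   # 1000
#' select_gprox(sw$dragons_core)    # 4
#' @export
example_sweeps <- function() {
  dragons_gprox <- 1:9
  dragons_full <- c(0.0001, 0.0004, 0.0010, 0.0018, 0.0031,
                    0.0048, 0.0071, 0.0105, 0.0147)
  dragons_core <- c(0.0001, 0.0004, 0.0010, 0.0018, 0.0030,
                    0.0047, 0.0067, 0.0090, 0.0115)
  dolphins_gprox <- seq(600, 1400, by = 100)
  dolphins_full <- c(0.0145, 0.0214, 0.0307, 0.0416, 0.0543,
                     0.0672, 0.0836, 0.0956, 0.1071)
  dolphins_core <- c(0.0120, 0.0181, 0.0233, 0.0316, 0.0397,
                     0.0488, 0.0576, 0.0658, 0.0717)
  list(
    dragons_full = sweep_table(dragons_gprox, dragons_full,
                               observed_mean_hwi = 0.0034),
    dragons_core = sweep_table(dragons_gprox, dragons_core,
                               observed_mean_hwi = 0.0020),
    dolphins_full = sweep_table(dolphins_gprox, dolphins_full,
                                observed_mean_hwi = 0.0604),
    dolphins_core = sweep_table(dolphins_gprox, dolphins_core,
                                observed_mean_hwi = 0.0525)
  )
}
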