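#' Leave one region's trends in place, detrend all others
#'
#' Builds the mixed cube of the leave-one-region-undetrended experiment:
#' cells of the `keep` region retain their original series, all other
#' breadbasket cells are replaced by their detrend-both transform, and cells
#' outside every region are untouched bit-exactly (they never enter area
#' computations).
#'
#' @param cube A [smile_cube()].
#' @param regions A [region_set()].
#' @param keep Region name whose trends are retained.
#' @param window,ref_period,sd_floor As in [detrend_cube()].
#' @param detrended Optional precomputed `detrend_both(cube, ...)` result, to
#'   share across the six experiments.
#' @return A [smile_cube()].
#' @export
leave_one_region_undetrended <- function(cube, regions, keep, window = 31,
                                         ref_period = c(1850, 1899),
                                         sd_floor = 1e-12, detrended = NULL) {
  stopifnot(inherits(cube, "smile_cube"), inherits(regions, "region_set"))
  if (!keep %in% names(regions$cells)) {
    stop(sprintf("unknown region '%s'; expected one of: %s", keep,
                 paste(names(regions$cells), collapse = ", ")), call. = FALSE)
  }
  dt <- detrended %||% detrend_cube(cube, "both", window = window,
                                    ref_period = ref_period, sd_floor = sd_floor)
  other <- setdiff(regions$global_cells, regions$cells[[keep]])
  out <- cube$values
  out[, , other] <- dt$values[, , other]
  smile_cube(out, cube$years, cube$grid, units = cube$units,
             var_name = cube$var_name,
             provenance = c(cube$provenance,
                            sprintf("leave-one-region-undetrended: keep '%s'", keep)))
}

# Shared helper: global record-shattering events of a (possibly transformed)
# cube, with the baseline refit on the cube's own reference-period pool.
global_record_events <- function(cube, regions, margin = 5, percentile = 20,
                                 ref_period = c(1850, 1899), tracking_start = NULL) {
  bl <- fit_baseline(cube, ref_period = ref_period, percentile = percentile)
  area <- drought_area(classify_drought(cube, bl), regions, scope = "global")
  record_events(area, margin = margin, tracking_start = tracking_start)
}

#' Regional trend contributions to global record-shattering risk
#'
#' For one model's ensemble, quantifies each region's soil-moisture-trend
#' contribution to the probability of at least one global record-shattering
#' drought in `period`: the leave-one-region-undetrended probability minus
#' the detrend-all (stationary) probability. The original (non-detrended)
#' and detrend-all probabilities are attached for reference.
#'
#' @param cube A [smile_cube()].
#' @param regions A [region_set()].
#' @param period Inclusive years, e.g. `c(2026, 2099)`.
#' @param margin Record-shattering margin (pp of breadbasket area).
#' @param percentile Drought percentile.
#' @param window,ref_period As in [detrend_cube()].
#' @return Tibble `region`, `probability` (leave-one), `contribution`,
#'   `p_original`, `p_detrend_all`.
#' @export
regional_contributions <- function(cube, regions, period = c(2026, 2099),
                                   margin = 5, percentile = 20, window = 31,
                                   ref_period = c(1850, 1899)) {
  stopifnot(inherits(cube, "smile_cube"))
  dt <- detrend_cube(cube, "both", window = window, ref_period = ref_period)
  p_orig <- prob_at_least_one(
    global_record_events(cube, regions, margin, percentile, ref_period), period)
  p_all <- prob_at_least_one(
    global_record_events(dt, regions, margin, percentile, ref_period), period)
  purrr::map_dfr(names(regions$cells), function(rn) {
    mix <- leave_one_region_undetrended(cube, regions, rn, window = window,
                                        ref_period = ref_period, detrended = dt)
    p <- prob_at_least_one(
      global_record_events(mix, regions, margin, percentile, ref_period), period)
    tibble::tibble(region = rn, probability = p, contribution = p - p_all,
                   p_original = p_orig, p_detrend_all = p_all)
  })
}
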