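#' Drought-area series for model evaluation
#'
#' Runs the standard classification pipeline with a modern reference window:
#' grid-point droughts defined against the pooled 1980-2009 percentile
#' baseline, drought area computed for 1980-2024 — the configuration under
#' which simulated drought-area variability and trends can be compared with
#' observational and reanalysis datasets (for a single-realization reference
#' dataset the "pool" is that one realization). No detrending is applied:
#' evaluation looks at raw drought-area behaviour.
#'
#' @param cube A [smile_cube()] covering the evaluation period.
#' @param regions A [region_set()].
#' @param ref_period Reference years for the percentile baseline.
#' @param eval_period Years over which drought area is reported.
#' @param percentile Drought percentile (default 20).
#' @param scope Scopes to report (default all regions plus `"global"`).
#' @return A [drought_area()] tibble restricted to `eval_period`.
#' @export
eval_drought_area <- function(cube, regions, ref_period = c(1980, 2009),
                              eval_period = c(1980, 2024), percentile = 20,
                              scope = NULL) {
  stopifnot(inherits(cube, "smile_cube"))
  if (ref_period[1] < eval_period[1] && ref_period[1] < min(cube$years)) {
    stop("reference period not covered by the input", call. = FALSE)
  }
  period_index(cube, eval_period)   # errors on coverage gaps
  bl <- fit_baseline(cube, ref_period = ref_period, percentile = percentile)
  area <- drought_area(classify_drought(cube, bl), regions, scope = scope)
  area[area$year >= eval_period[1] & area$year <= eval_period[2], ]
}

#' Linear drought-area trends per member
#'
#' OLS slope of annual drought area on year for each member (and scope),
#' scaled to percent per decade — one of the two key drivers of
#' record-shattering probabilities compared against observations.
#'
#' @param area_tbl A drought-area tibble (`member`, `year`, `area`, optional
#'   `scope`).
#' @param period Optional inclusive year range to fit over.
#' @return Tibble `scope` (if present), `member`, `slope` (% per decade).
#' @export
area_linear_trend <- function(area_tbl, period = NULL) {
  stopifnot(all(c("member", "year", "area") %in% names(area_tbl)))
  if (!is.null(period)) {
    area_tbl <- area_tbl[area_tbl$year >= period[1] & area_tbl$year <= period[2], ]
  }
  grouping <- intersect(c("scope", "member"), names(area_tbl))
  area_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(slope = ols_slope(.data$year, .data$area) * 10,
                     .groups = "drop")
}

ols_slope <- function(x, y) {
  if (length(x) < 3) stop("at least 3 years are required for a trend", call. = FALSE)
  if (stats::var(x) == 0) stop("time axis is constant; no trend can be fit", call. = FALSE)
  stats::cov(x, y) / stats::var(x)
}

#' Model-level trend summary
#'
#' Summarizes member-level drought-area trends at the model level: mean
#' across members, with the member spread as the standard deviation of the
#' estimated trends.
#'
#' @param trend_tbl An [area_linear_trend()] result.
#' @return Tibble `scope` (if present), `mean_slope`, `sd_slope`,
#'   `n_members`.
#' @export
trend_summary <- function(trend_tbl) {
  grouping <- intersect("scope", names(trend_tbl))
  trend_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(mean_slope = mean(.data$slope),
                     sd_slope = stats::sd(.data$slope),
                     n_members = dplyr::n(), .groups = "drop")
}

#' Interannual variability of drought area
#'
#' Sample (n-1) standard deviation of annual drought area per member (and
#' scope) over the evaluation period.
#'
#' @inheritParams area_linear_trend
#' @return Tibble `scope` (if present), `member`, `sd_area`.
#' @export
interannual_sd <- function(area_tbl, period = NULL) {
  stopifnot(all(c("member", "year", "area") %in% names(area_tbl)))
  if (!is.null(period)) {
    area_tbl <- area_tbl[area_tbl$year >= period[1] & area_tbl$year <= period[2], ]
  }
  grouping <- intersect(c("scope", "member"), names(area_tbl))
  area_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(sd_area = stats::sd(.data$area), .groups = "drop")
}

#' Agreement with a reference's uncertainty band
#'
#' Pure predicate: does a model's summarized value fall within the
#' reference's value +/- its stated standard deviation? No hidden tolerance.
#'
#' @param model_value,ref_value,ref_sd Numerics (vectorized).
#' @return Logical.
#' @export
within_reference_band <- function(model_value, ref_value, ref_sd) {
  abs(model_value - ref_value) <= ref_sd
}
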