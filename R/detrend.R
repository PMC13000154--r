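#' Pooled moving-window mean and SD
#'
#' For every year and grid cell, the mean and sample standard deviation of
#' annual soil moisture over the `window`-year window centered on that year,
#' pooling all ensemble members jointly — the slowly varying "current
#' climate" moments the detrending experiments stationarize. Edge windows are
#' clipped to the data span by default (shrinking to at least
#' `(window + 1) / 2` years), keeping the full record usable; `edges =
#' "full"` restricts output to complete windows.
#'
#' @param cube A [smile_cube()].
#' @param window Odd window length in years (31 by default, i.e. +/-15).
#' @param edges `"clip"` or `"full"`.
#' @return An object of class `moving_stats`: list with `mean` and `sd`
#'   (`n_years x n_cells` matrices; rows of excluded edge years are `NA`
#'   under `edges = "full"`), `years`, `window`, `n_members`.
#' @export
pooled_moving_stats <- function(cube, window = 31, edges = c("clip", "full")) {
  stopifnot(inherits(cube, "smile_cube"))
  edges <- match.arg(edges)
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  d <- dim(cube$values)
  if (window > d[2]) stop("window is larger than the year span", call. = FALSE)
  m <- d[1]
  s1 <- colSums(cube$values)            # year x cell sums over members
  s2 <- colSums(cube$values^2)
  cs1 <- rbind(0, apply(s1, 2, cumsum))
  cs2 <- rbind(0, apply(s2, 2, cumsum))
  h <- (window - 1) / 2
  lo <- pmax(seq_len(d[2]) - h, 1)
  hi <- pmin(seq_len(d[2]) + h, d[2])
  w1 <- cs1[hi + 1, , drop = FALSE] - cs1[lo, , drop = FALSE]
  w2 <- cs2[hi + 1, , drop = FALSE] - cs2[lo, , drop = FALSE]
  n <- (hi - lo + 1) * m
  mu <- w1 / n
  var <- (w2 - w1^2 / n) / (n - 1)
  sd <- sqrt(pmax(var, 0))
  if (edges == "full") {
    drop_rows <- (hi - lo + 1) < window
    mu[drop_rows, ] <- NA_real_
    sd[drop_rows, ] <- NA_real_
  }
  structure(list(mean = mu, sd = sd, years = cube$years, window = window,
                 n_members = m),
            class = "moving_stats")
}

#' @export
print.moving_stats <- function(x, ...) {
  cat(sprintf("<moving_stats> %d-year pooled window, %d members, years %d-%d\n",
              x$window, x$n_members, min(x$years), max(x$years)))
  invisible(x)
}

pooled_ref_stats <- function(cube, ref_period) {
  idx <- period_index(cube, ref_period)
  pooled <- cube$values[, idx, , drop = FALSE]
  d <- dim(pooled)
  flat <- matrix(pooled, d[1] * d[2], d[3])
  list(mean = colMeans(flat), sd = apply(flat, 2, stats::sd))
}

broadcast_year_cell <- function(mat, n_members) {
  aperm(array(mat, c(dim(mat), n_members)), c(3, 1, 2))
}

#' Detrending experiments on an ensemble cube
#'
#' Transforms each member/cell/year using the pooled moving-window moments so
#' that the mean and/or standard deviation of soil moisture are pinned to
#' their pooled preindustrial (`ref_period`) values:
#'
#' * `detrend_mean()`: `x - movmean + refmean` — removes the long-term mean
#'   trend, preserves the variability evolution.
#' * `detrend_sd()`: `(x - movmean) / movsd * refsd + movmean` — removes the
#'   variability trend, preserves the mean evolution (the pooled window mean
#'   is added back, so the pooled mean is preserved algebraically).
#' * `detrend_both()`: `(x - movmean) / movsd * refsd + refmean` — a series
#'   stationary at the preindustrial mean and SD.
#'
#' A pooled window SD below `sd_floor * refsd` raises an error naming the
#' year and cell rather than silently inflating anomalies.
#'
#' @param cube A [smile_cube()].
#' @param mode `"mean"`, `"sd"`, `"both"` or `"none"` (identity).
#' @param window Odd moving-window length (31 by default).
#' @param ref_period Preindustrial reference years, default 1850-1899.
#' @param sd_floor Relative degenerate-SD threshold.
#' @param moving Optional precomputed [pooled_moving_stats()] (must match
#'   `window`); avoids recomputation across experiments.
#' @return A [smile_cube()] with provenance noting the experiment.
#' @export
detrend_cube <- function(cube, mode = c("both", "mean", "sd", "none"),
                         window = 31, ref_period = c(1850, 1899),
                         sd_floor = 1e-12, moving = NULL) {
  stopifnot(inherits(cube, "smile_cube"))
  mode <- match.arg(mode)
  if (mode == "none") return(cube_note(cube, "detrend experiment: none (original)"))
  ms <- moving %||% pooled_moving_stats(cube, window = window)
  if (!identical(ms$window, window)) stop("`moving` was computed with a different window", call. = FALSE)
  rf <- pooled_ref_stats(cube, ref_period)
  d <- dim(cube$values)
  movmean <- broadcast_year_cell(ms$mean, d[1])
  refmean <- aperm(array(rf$mean, c(d[3], d[1], d[2])), c(2, 3, 1))
  if (mode == "mean") {
    out <- cube$values - movmean + refmean
  } else {
    floor_mat <- matrix(rf$sd * sd_floor, d[2], d[3], byrow = TRUE)
    bad <- which(ms$sd <= floor_mat, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("degenerate pooled window SD at year %d, cell %d (and %d more)",
                   cube$years[bad[1, 1]], bad[1, 2], nrow(bad) - 1), call. = FALSE)
    }
    scale <- broadcast_year_cell(
      ms$sd / matrix(rf$sd, d[2], d[3], byrow = TRUE), d[1])
    anom <- (cube$values - movmean) / scale
    out <- if (mode == "sd") anom + movmean else anom + refmean
  }
  smile_cube(out, cube$years, cube$grid, units = cube$units,
             var_name = cube$var_name,
             provenance = c(cube$provenance,
                            sprintf("detrend experiment: %s (window %d, ref %d-%d)",
                                    mode, window, ref_period[1], ref_period[2])))
}

#' @rdname detrend_cube
#' @param ... Passed on to [detrend_cube()].
#' @export
detrend_mean <- function(cube, ...) detrend_cube(cube, mode = "mean", ...)

#' @rdname detrend_cube
#' @export
detrend_sd <- function(cube, ...) detrend_cube(cube, mode = "sd", ...)

#' @rdname detrend_cube
#' @export
detrend_both <- function(cube, ...) detrend_cube(cube, mode = "both", ...)

#' Decompose drought-area change into mean and variability contributions
#'
#' For the original data and each detrending experiment, computes the change
#' in mean annual drought area between a future period and the preindustrial
#' baseline period (per member, then averaged over members). The contribution
#' of the mean trend is the change remaining in the detrend-SD experiment,
#' that of variability the change remaining in the detrend-mean experiment,
#' and the detrend-both experiment is the stationary control (change ~ 0).
#' Thresholds are refit on each transformed cube's own reference-period pool
#' (`refit_baseline = FALSE` reuses the original baseline instead).
#'
#' @param cube A [smile_cube()].
#' @param regions A [region_set()].
#' @param future_period E.g. `c(2026, 2055)` or `c(2026, 2099)`.
#' @param baseline_period Reference period, default 1850-1899.
#' @param percentile Drought percentile (default 20).
#' @param scope Scopes to report (default all regions plus `"global"`).
#' @param window Moving-window length for the experiments.
#' @param refit_baseline Refit thresholds on each transformed cube.
#' @return Tibble `experiment` (`original`, `detrend_mean`, `detrend_sd`,
#'   `detrend_both`), `scope`, `delta_area` (pp), `future_mean`,
#'   `baseline_mean`.
#' @export
area_change_decomposition <- function(cube, regions, future_period,
                                      baseline_period = c(1850, 1899),
                                      percentile = 20, scope = NULL,
                                      window = 31, refit_baseline = TRUE) {
  stopifnot(inherits(cube, "smile_cube"))
  ms <- pooled_moving_stats(cube, window = window)
  base0 <- fit_baseline(cube, ref_period = baseline_period, percentile = percentile)
  experiments <- c("original", "detrend_mean", "detrend_sd", "detrend_both")
  purrr::map_dfr(experiments, function(ex) {
    tc <- switch(ex,
      original = cube,
      detrend_mean = detrend_cube(cube, "mean", window = window,
                                  ref_period = baseline_period, moving = ms),
      detrend_sd = detrend_cube(cube, "sd", window = window,
                                ref_period = baseline_period, moving = ms),
      detrend_both = detrend_cube(cube, "both", window = window,
                                  ref_period = baseline_period, moving = ms))
    bl <- if (refit_baseline && ex != "original")
      fit_baseline(tc, ref_period = baseline_period, percentile = percentile)
      else base0
    area <- drought_area(classify_drought(tc, bl), regions, scope = scope)
    area |>
      dplyr::group_by(.data$scope, .data$member) |>
      dplyr::summarise(
        future = mean(.data$area[.data$year >= future_period[1] &
                                   .data$year <= future_period[2]]),
        base = mean(.data$area[.data$year >= baseline_period[1] &
                                 .data$year <= baseline_period[2]]),
        .groups = "drop") |>
      dplyr::group_by(.data$scope) |>
      dplyr::summarise(delta_area = mean(.data$future - .data$base),
                       future_mean = mean(.data$future),
                       baseline_mean = mean(.data$base), .groups = "drop") |>
      dplyr::mutate(experiment = ex, .before = 1)
  })
}
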