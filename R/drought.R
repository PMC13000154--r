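#' Fit a pooled percentile drought baseline
#'
#' For each grid cell, pools all ensemble members over the reference period
#' (default the preindustrial half-century 1850-1899) and records the
#' empirical percentile threshold below which a year counts as drought, plus
#' the pooled mean and standard deviation used for standardized anomalies.
#' The percentile estimator interpolates linearly between order statistics
#' (the common "type 7" default; switchable via `type`).
#'
#' @param cube A [smile_cube()].
#' @param ref_period Inclusive year range `c(first, last)`; default 1850-1899.
#' @param percentile Drought percentile in (0, 100); 20 for moderate drought,
#'   5 for the restrictive definition.
#' @param type Quantile estimator type passed to [stats::quantile()].
#' @return An object of class `drought_baseline` with a per-cell tibble
#'   (`cell`, `threshold`, `mean`, `sd`, `degenerate`) and the fit metadata.
#' @export
fit_baseline <- function(cube, ref_period = c(1850, 1899), percentile = 20,
                         type = 7) {
  stopifnot(inherits(cube, "smile_cube"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  idx <- period_index(cube, ref_period)
  pooled <- cube$values[, idx, , drop = FALSE]
  d <- dim(pooled)
  flat <- matrix(pooled, d[1] * d[2], d[3])
  thr <- apply(flat, 2, stats::quantile, probs = percentile / 100,
               type = type, names = FALSE)
  mu <- colMeans(flat)
  sdev <- apply(flat, 2, stats::sd)
  structure(
    list(
      stats = tibble::tibble(cell = seq_len(d[3]), threshold = thr,
                             mean = mu, sd = sdev, degenerate = sdev == 0),
      ref_period = as.integer(ref_period), percentile = percentile,
      type = type, n_pooled = d[1] * d[2], grid = cube$grid
    ),
    class = "drought_baseline"
  )
}

#' @export
print.drought_baseline <- function(x, ...) {
  cat(sprintf("<drought_baseline> p%g over %d-%d (pooled n = %d per cell)\n",
              x$percentile, x$ref_period[1], x$ref_period[2], x$n_pooled))
  if (any(x$stats$degenerate)) {
    cat(sprintf("  %d cell(s) with zero pooled SD (flagged degenerate)\n",
                sum(x$stats$degenerate)))
  }
  invisible(x)
}

#' @rdname fit_baseline
#' @param x A `drought_baseline`.
#' @param ... Unused.
#' @method tidy drought_baseline
#' @export
tidy.drought_baseline <- function(x, ...) x$stats

#' @rdname fit_baseline
#' @method glance drought_baseline
#' @export
glance.drought_baseline <- function(x, ...) {
  tibble::tibble(percentile = x$percentile, ref_start = x$ref_period[1],
                 ref_end = x$ref_period[2], n_pooled = x$n_pooled,
                 n_degenerate = sum(x$stats$degenerate))
}

#' Classify grid-cell droughts
#'
#' A cell-year is under drought when annual soil moisture falls strictly below
#' the cell's baseline percentile threshold ("falls below": values exactly at
#' the threshold are not drought).
#'
#' @param cube A [smile_cube()].
#' @param baseline A [fit_baseline()] result on the same grid.
#' @return A `drought_mask`: logical array `(member, year, cell)` carrying the
#'   cube's year axis and grid.
#' @export
classify_drought <- function(cube, baseline) {
  stopifnot(inherits(cube, "smile_cube"), inherits(baseline, "drought_baseline"))
  if (!grids_identical(cube$grid, baseline$grid)) {
    stop("baseline grid does not match the cube grid", call. = FALSE)
  }
  d <- dim(cube$values)
  thr <- aperm(array(baseline$stats$threshold, c(d[3], d[1], d[2])), c(2, 3, 1))
  mask <- cube$values < thr
  structure(list(mask = mask, years = cube$years, grid = cube$grid),
            class = "drought_mask")
}

#' @export
print.drought_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<drought_mask> %d members x %d years x %d cells (%.1f%% under drought)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Regional and global drought-area series
#'
#' For each member and year, the drought area of a scope is the area-weighted
#' fraction (in %) of that scope's cells under drought. `denominator`
#' controls the reference area: `"regional"` divides by the scope's own area,
#' `"global"` by the total breadbasket area, so the six regional
#' global-denominator series sum to the global series. Cell weights are
#' cos-latitude area weights by default; `equal_weights = TRUE` counts cells
#' equally instead.
#'
#' @param mask A [classify_drought()] result.
#' @param regions A [region_set()] on the same grid.
#' @param scope `"global"`, a region name, or a character vector of scopes
#'   (default: all regions plus `"global"`).
#' @param denominator `"regional"` or `"global"`; the global scope always
#'   uses the breadbasket denominator.
#' @param equal_weights Use equal cell weights instead of area weights.
#' @return Tibble with columns `member`, `year`, `scope`, `denominator`,
#'   `area` (percent in `[0, 100]`).
#' @export
drought_area <- function(mask, regions, scope = NULL,
                         denominator = c("regional", "global"),
                         equal_weights = FALSE) {
  stopifnot(inherits(mask, "drought_mask"), inherits(regions, "region_set"))
  if (!grids_identical(mask$grid, regions$grid)) {
    stop("mask grid does not match the region grid", call. = FALSE)
  }
  denominator <- match.arg(denominator)
  if (is.null(scope)) scope <- c(names(regions$cells), "global")
  w <- if (equal_weights) rep(1, length(regions$weights)) else regions$weights
  d <- dim(mask$mask)
  flat <- matrix(mask$mask, d[1] * d[2], d[3])
  denom_cells_global <- regions$global_cells
  purrr::map_dfr(scope, function(sc) {
    sel <- region_cells(regions, sc)
    den <- if (identical(sc, "global")) "global" else denominator
    den_cells <- if (den == "global") denom_cells_global else sel
    num <- as.vector(flat[, sel, drop = FALSE] %*% w[sel])
    area <- 100 * num / sum(w[den_cells])
    tibble::tibble(
      member = rep(seq_len(d[1]), times = d[2]),
      year = rep(mask$years, each = d[1]),
      scope = sc, denominator = den, area = area
    )
  })
}

#' Mean drought intensity of drought-affected cells
#'
#' The area-weighted mean standardized soil-moisture anomaly (in baseline
#' sigma units) over all cells classified as under drought in a member-year;
#' years with no drought cells in scope get `NA` (an explicit missing marker,
#' not zero). Anomalies are taken relative to the baseline's pooled
#' preindustrial mean and SD.
#'
#' @param cube A [smile_cube()].
#' @param mask The matching [classify_drought()] result.
#' @param baseline The [fit_baseline()] used for the mask.
#' @param regions A [region_set()]; intensity is evaluated over the
#'   breadbasket union (or one region via `scope`).
#' @param scope `"global"` or a region name.
#' @param equal_weights Use equal cell weights.
#' @return Tibble `member`, `year`, `scope`, `intensity`.
#' @export
drought_intensity <- function(cube, mask, baseline, regions, scope = "global",
                              equal_weights = FALSE) {
  stopifnot(inherits(cube, "smile_cube"), inherits(mask, "drought_mask"))
  sel <- region_cells(regions, scope)
  sdv <- baseline$stats$sd[sel]
  if (any(sdv == 0)) {
    hit <- apply(mask$mask[, , sel[sdv == 0], drop = FALSE], 3, any)
    if (any(hit)) {
      stop(sprintf("baseline SD is zero on drought-affected cell(s): %s",
                   paste(sel[sdv == 0][hit], collapse = ", ")), call. = FALSE)
    }
  }
  w <- if (equal_weights) rep(1, length(regions$weights)) else regions$weights
  d <- dim(cube$values)
  anom <- sweep(sweep(cube$values[, , sel, drop = FALSE], 3,
                      baseline$stats$mean[sel], "-"),
                3, ifelse(sdv == 0, 1, sdv), "/")
  mflat <- matrix(mask$mask[, , sel, drop = FALSE], d[1] * d[2], length(sel))
  aflat <- matrix(anom, d[1] * d[2], length(sel))
  wnum <- (aflat * mflat) %*% w[sel]
  wden <- mflat %*% w[sel]
  intensity <- ifelse(wden > 0, wnum / wden, NA_real_)
  tibble::tibble(
    member = rep(seq_len(d[1]), times = d[2]),
    year = rep(cube$years, each = d[1]),
    scope = scope, intensity = as.vector(intensity)
  )
}
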