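#' Ensemble soil-moisture cube
#'
#' A `smile_cube` stores one model's large-ensemble annual surface soil
#' moisture as a dense array indexed `(member, year, cell)`, together with its
#' grid, units and a provenance trail of the transformations applied to it.
#' Monthly data are held in the companion class `smile_cube_monthly` (same
#' layout with a time axis carrying `year` and `month`) until annualized with
#' [annual_mean()].
#'
#' @param values Numeric array `n_members x n_years x n_cells`.
#' @param years Integer vector of calendar years (one per time slice).
#' @param grid A [grid_spec()].
#' @param units Units label for the variable (default `"kg m-2"`, the
#'   conventional unit of surface soil moisture content).
#' @param var_name Variable name used on disk (default `"mrsos"`).
#' @param provenance Character vector of transformation notes.
#' @return An object of class `smile_cube`.
#' @export
smile_cube <- function(values, years, grid, units = "kg m-2",
                       var_name = "mrsos", provenance = character()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dim(values)) != 3) stop("values must be a 3-d (member, year, cell) array", call. = FALSE)
  if (dim(values)[2] != length(years)) stop("year axis does not match values", call. = FALSE)
  if (dim(values)[3] != n_cells(grid)) stop("cell axis does not match the grid", call. = FALSE)
  years <- as.integer(years)
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing", call. = FALSE)
  structure(
    list(values = values, years = years, grid = grid, units = units,
         var_name = var_name, provenance = as.character(provenance)),
    class = "smile_cube"
  )
}

#' @export
print.smile_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<smile_cube> %d members x %d years (%d-%d) x %d cells [%s]\n",
              d[1], d[2], min(x$years), max(x$years), d[3], x$units))
  if (length(x$provenance)) cat("provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.smile_cube <- function(x) dim(x$values)

n_members <- function(cube) dim(cube$values)[1]

cube_note <- function(cube, note) {
  cube$provenance <- c(cube$provenance, note)
  cube
}

year_index <- function(cube, years) {
  idx <- match(as.integer(years), cube$years)
  if (anyNA(idx)) {
    stop(sprintf("years %s not present in the cube (%d-%d)",
                 paste(years[is.na(idx)], collapse = ", "),
                 min(cube$years), max(cube$years)), call. = FALSE)
  }
  idx
}

period_index <- function(cube, period) {
  period <- as.integer(period)
  stopifnot(length(period) == 2, period[1] <= period[2])
  if (period[1] < min(cube$years) || period[2] > max(cube$years)) {
    stop(sprintf("period %d-%d is not covered by the cube (%d-%d)",
                 period[1], period[2], min(cube$years), max(cube$years)),
         call. = FALSE)
  }
  which(cube$years >= period[1] & cube$years <= period[2])
}

#' Convert a cube to a long tibble
#'
#' One row per `(member, year, cell)`; convenient for dplyr/ggplot2 work on
#' small cubes (the full array is expanded).
#'
#' @param x A `smile_cube`.
#' @param ... Unused.
#' @return Tibble with columns `member`, `year`, `cell`, `lat`, `lon`, `value`.
#' @method as_tibble smile_cube
#' @export
as_tibble.smile_cube <- function(x, ...) {
  d <- dim(x$values)
  tab <- grid_cells(x$grid)
  tibble::tibble(
    member = rep(seq_len(d[1]), times = d[2] * d[3]),
    year = rep(rep(x$years, each = d[1]), times = d[3]),
    cell = rep(tab$cell, each = d[1] * d[2]),
    lat = rep(tab$lat, each = d[1] * d[2]),
    lon = rep(tab$lon, each = d[1] * d[2]),
    value = as.vector(x$values)
  )
}

#' Monthly ensemble cube
#'
#' @param values Numeric array `n_members x n_time x n_cells`.
#' @param year,month Integer vectors along the time axis.
#' @inheritParams smile_cube
#' @return An object of class `smile_cube_monthly`.
#' @export
smile_cube_monthly <- function(values, year, month, grid, units = "kg m-2",
                               var_name = "mrsos", provenance = character()) {
  stopifnot(inherits(grid, "grid_spec"),
            length(dim(values)) == 3,
            dim(values)[2] == length(year), length(year) == length(month))
  structure(
    list(values = values, year = as.integer(year), month = as.integer(month),
         grid = grid, units = units, var_name = var_name,
         provenance = as.character(provenance)),
    class = "smile_cube_monthly"
  )
}

#' Annualize a monthly cube by calendar-year means
#'
#' Produces one value per `(member, year, cell)` as the equal-weight mean of
#' that calendar year's 12 months. Every year must be complete; an incomplete
#' year raises an error naming it. Month-length (day) weighting is available
#' via `month_weights` for users who prefer a day-weighted annual mean.
#'
#' @param monthly A [smile_cube_monthly()].
#' @param month_weights Optional length-12 numeric weights (e.g. days per
#'   month); default equal weights.
#' @return A [smile_cube()].
#' @export
annual_mean <- function(monthly, month_weights = NULL) {
  stopifnot(inherits(monthly, "smile_cube_monthly"))
  yrs <- sort(unique(monthly$year))
  counts <- table(factor(monthly$year, levels = yrs))
  bad <- yrs[counts != 12L]
  if (length(bad)) {
    stop(sprintf("incomplete calendar year(s): %s (need 12 months each)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(month_weights)) month_weights <- rep(1, 12)
  stopifnot(length(month_weights) == 12, all(month_weights > 0))
  d <- dim(monthly$values)
  out <- array(NA_real_, c(d[1], length(yrs), d[3]))
  for (i in seq_along(yrs)) {
    sel <- which(monthly$year == yrs[i])
    sel <- sel[order(monthly$month[sel])]
    w <- month_weights / sum(month_weights)
    slab <- monthly$values[, sel, , drop = FALSE]
    acc <- array(0, c(d[1], 1, d[3]))
    for (k in 1:12) acc <- acc + w[k] * slab[, k, , drop = FALSE]
    out[, i, ] <- acc
  }
  smile_cube(out, yrs, monthly$grid, units = monthly$units,
             var_name = monthly$var_name,
             provenance = c(monthly$provenance, "annual calendar-year mean"))
}

#' Restrict a cube to a year range
#'
#' @param cube A `smile_cube`.
#' @param period Inclusive `c(first, last)` year range.
#' @return A `smile_cube` covering only `period`.
#' @export
subset_years <- function(cube, period) {
  idx <- period_index(cube, period)
  smile_cube(cube$values[, idx, , drop = FALSE], cube$years[idx], cube$grid,
             units = cube$units, var_name = cube$var_name,
             provenance = c(cube$provenance,
                            sprintf("subset to %d-%d", period[1], period[2])))
}
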