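#' Record-breaking and record-shattering events in one series
#'
#' Scans a single member's annual drought-area series. The running maximum is
#' initialized at the first tracked year, which is never itself an event (a
#' previous record must exist). With `margin > 0`, year `y` is a
#' record-shattering event when `value(y) >= running_max + margin`
#' (percentage points of the scope's area, absolute — not relative to the old
#' record); with `margin = 0`, a record-breaking event when
#' `value(y) > running_max`. The running maximum updates whenever a value
#' exceeds it, event or not.
#'
#' @param values Numeric series of annual drought areas.
#' @param years Optional calendar years (default `1, 2, ...`).
#' @param margin Exceedance margin in percentage points (`>= 0`); 5 is the
#'   headline record-shattering definition, 0 gives ordinary record-breaking.
#' @param tracking_start Year tracking starts from (default the first year).
#' @return Tibble `year`, `value`, `exceedance`, `type` (one row per event).
#' @examples
#' find_record_events(c(10, 12, 18, 15, 24), margin = 5)
#' @export
find_record_events <- function(values, years = seq_along(values), margin = 5,
                               tracking_start = NULL) {
  if (length(values) < 2) stop("a series of at least 2 years is required", call. = FALSE)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  stopifnot(length(years) == length(values))
  if (!is.null(tracking_start)) {
    keep <- years >= tracking_start
    values <- values[keep]; years <- years[keep]
    if (length(values) < 2) stop("fewer than 2 years after tracking_start", call. = FALSE)
  }
  run_max <- values[1]
  ev_year <- integer(); ev_val <- numeric(); ev_exc <- numeric()
  for (i in seq_along(values)[-1]) {
    v <- values[i]
    hit <- if (margin > 0) v >= run_max + margin else v > run_max
    if (hit) {
      ev_year <- c(ev_year, years[i]); ev_val <- c(ev_val, v)
      ev_exc <- c(ev_exc, v - run_max)
    }
    if (v > run_max) run_max <- v
  }
  tibble::tibble(year = ev_year, value = ev_val, exceedance = ev_exc,
                 type = if (margin > 0) "record-shattering" else "record-breaking")
}

#' Record events for every member of an area series
#'
#' Applies [find_record_events()] per member (and per scope, if the table
#' holds several) of a drought-area table as returned by [drought_area()].
#'
#' @param area_tbl Tibble with columns `member`, `year`, `area` (and
#'   optionally `scope`).
#' @inheritParams find_record_events
#' @return Tibble `scope` (if present), `member`, `year`, `value`,
#'   `exceedance`, `type`, with attributes `n_members` and `years` covering
#'   the full span scanned.
#' @export
record_events <- function(area_tbl, margin = 5, tracking_start = NULL) {
  stopifnot(all(c("member", "year", "area") %in% names(area_tbl)))
  grouping <- intersect(c("scope", "member"), names(area_tbl))
  out <- area_tbl |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grouping, "year")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::reframe(find_record_events(.data$area, .data$year, margin = margin,
                                      tracking_start = tracking_start))
  attr(out, "n_members") <- length(unique(area_tbl$member))
  attr(out, "years") <- range(area_tbl$year)
  attr(out, "margin") <- margin
  out
}

#' Moving-window annual probability of record events
#'
#' Within a `window`-year moving window (31 years, i.e. +/-15, by default)
#' centered on each year, the event count across all members is divided by
#' the total member-years in the window (`window * n_members`). By default
#' only center years whose full window lies inside the scanned span are
#' reported; `edges = "truncated"` instead divides by the actual member-years
#' of the clipped window so edge years are retained.
#'
#' @param events A [record_events()] table (one scope).
#' @param years Full year span scanned, `c(first, last)`; defaults to the
#'   attribute recorded by [record_events()].
#' @param n_members Ensemble size; defaults to the recorded attribute.
#' @param window Odd window length in years.
#' @param edges `"full"` or `"truncated"`.
#' @return Tibble `year`, `probability`, `n_events`, `window`, `n_members`.
#' @export
annual_probability <- function(events, years = NULL, n_members = NULL,
                               window = 31, edges = c("full", "truncated")) {
  edges <- match.arg(edges)
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  years <- years %||% attr(events, "years")
  n_members <- n_members %||% attr(events, "n_members")
  if (is.null(years) || is.null(n_members)) {
    stop("supply `years` and `n_members` (or pass a record_events() table)", call. = FALSE)
  }
  span <- seq(years[1], years[2])
  if (window > length(span)) stop("window is larger than the series", call. = FALSE)
  h <- (window - 1) / 2
  counts <- tabulate(match(events$year, span), nbins = length(span))
  cs <- c(0, cumsum(counts))
  centers <- seq_along(span)
  lo <- pmax(centers - h, 1); hi <- pmin(centers + h, length(span))
  n_ev <- cs[hi + 1] - cs[lo]
  len <- hi - lo + 1
  tb <- tibble::tibble(year = span, probability = n_ev / (len * n_members),
                       n_events = n_ev, window = window, n_members = n_members)
  if (edges == "full") tb <- tb[len == window, ]
  tb
}

#' Probability of at least one event in a period
#'
#' Fraction of ensemble members that experience at least one record
#' (shattering or breaking, per the events table) inside the inclusive
#' period — the paper-style multi-decadal risk measure (e.g. 2026-2055,
#' 2026-2099).
#'
#' @param events A [record_events()] table.
#' @param period Inclusive `c(first, last)` years.
#' @param n_members Ensemble size (defaults to the recorded attribute).
#' @return A single probability in `[0, 1]`.
#' @export
prob_at_least_one <- function(events, period, n_members = NULL) {
  n_members <- n_members %||% attr(events, "n_members")
  if (is.null(n_members) || n_members < 1) stop("n_members is required", call. = FALSE)
  span <- attr(events, "years")
  if (!is.null(span) && (period[1] < span[1] || period[2] > span[2])) {
    stop(sprintf("period %d-%d lies outside the scanned span %d-%d",
                 period[1], period[2], span[1], span[2]), call. = FALSE)
  }
  hit <- events$member[events$year >= period[1] & events$year <= period[2]]
  length(unique(hit)) / n_members
}

#' Multi-model mean and inter-model range
#'
#' Summarizes per-model values the way ensemble figures report uncertainty:
#' the unweighted mean across models plus the min-max inter-model range of
#' the per-model (ensemble-mean) values.
#'
#' @param values Numeric vector of per-model values (optionally named), or a
#'   tibble with a `model` column and a value column named by `col`.
#' @param col Value column when `values` is a data frame.
#' @return Tibble `mean`, `min`, `max`, `n_models`.
#' @examples
#' multimodel_summary(c(0.32, 0.80, 0.52))
#' @export
multimodel_summary <- function(values, col = "value") {
  if (is.data.frame(values)) values <- values[[col]]
  if (!length(values)) stop("at least one model value is required", call. = FALSE)
  tibble::tibble(mean = mean(values), min = min(values), max = max(values),
                 n_models = length(values))
}
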