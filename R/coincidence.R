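#' Moderately extreme regional droughts (trailing-window percentile)
#'
#' A region-year `Y` of a member is under a moderately extreme drought when
#' its regional drought area strictly exceeds the 80th percentile of that
#' member's own trailing distribution, years `Y - 30` through `Y` inclusive
#' (the current year is part of its reference pool) — i.e. the drought ranks
#' among the ~20% largest of the preceding three decades, relative to the
#' ongoing climatology. Only years with a full trailing window are evaluated.
#'
#' @param area_tbl Regional drought-area tibble ([drought_area()] output;
#'   regional denominator recommended).
#' @param window Trailing window length in years (31 values including `Y`).
#' @param percentile Trailing percentile (default 80).
#' @param type Quantile estimator type (same default as [fit_baseline()]).
#' @return Tibble `scope`, `member`, `year`, `area`, `moderate` (logical).
#' @export
moderate_drought_flags <- function(area_tbl, window = 31, percentile = 80,
                                   type = 7) {
  stopifnot(all(c("member", "year", "area") %in% names(area_tbl)))
  grouping <- intersect(c("scope", "member"), names(area_tbl))
  area_tbl |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(grouping, "year")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::reframe({
      v <- .data$area; yr <- .data$year
      n <- length(v)
      flag <- rep(NA, n)
      for (i in seq_len(n)) {
        if (i >= window) {
          pool <- v[(i - window + 1):i]
          flag[i] <- v[i] > stats::quantile(pool, percentile / 100,
                                            type = type, names = FALSE)
        }
      }
      tibble::tibble(year = yr, area = v, moderate = flag)
    }) |>
    dplyr::filter(!is.na(.data$moderate))
}

#' @rdname moderate_drought_flags
#' @param member,year Single member id and year `Y` to evaluate.
#' @return `is_moderately_extreme()`: a single logical.
#' @export
is_moderately_extreme <- function(area_tbl, member, year, window = 31,
                                  percentile = 80, type = 7) {
  sel <- area_tbl[area_tbl$member == member, ]
  sel <- sel[order(sel$year), ]
  i <- match(year, sel$year)
  if (is.na(i)) stop(sprintf("year %d not present for member %s", year, member), call. = FALSE)
  if (i < window) {
    stop(sprintf("insufficient history: year %d needs %d trailing years", year, window),
         call. = FALSE)
  }
  pool <- sel$area[(i - window + 1):i]
  sel$area[i] > stats::quantile(pool, percentile / 100, type = type, names = FALSE)
}

#' Classify global record-shattering events by regional co-occurrence
#'
#' Assigns each global record-shattering event-year (per member) to exactly
#' one category by counting how many regions are simultaneously flagged in
#' the same member-year: `"0 regions"`, single-region cases split into
#' `"<region> only"` for the highlighted regions and `"Rest only"` for the
#' others, then `"2 regions"` ... `"6 regions"`. Categories are mutually
#' exclusive, so fractions sum to 100%.
#'
#' @param global_events Global [record_events()] table (columns `member`,
#'   `year`).
#' @param regional_flags Tibble `scope`, `member`, `year` of flagged
#'   region-years: either regional record-shattering event years (mode
#'   `"record-shattering"`) or [moderate_drought_flags()] rows with
#'   `moderate == TRUE` (mode `"moderately-extreme"`).
#' @param period Analysis period for global events (default 2000-2099).
#' @param highlight Regions given their own single-region category.
#' @param regions Character vector of all region names (defaults to those
#'   present in `regional_flags`; pass explicitly if some regions never flag).
#' @param mode Label recorded in the output.
#' @return A `coincidence_table` tibble `category`, `n_events`, `fraction`
#'   (percent), `mode`, with attribute `n_global_events`. With zero global
#'   events in the period, a zero-row table with attribute
#'   `status = "no-global-events"` is returned (never NaN fractions).
#' @export
classify_global_events <- function(global_events, regional_flags,
                                   period = c(2000, 2099),
                                   highlight = c("Europe", "USA", "Brazil"),
                                   regions = NULL,
                                   mode = c("record-shattering", "moderately-extreme")) {
  mode <- match.arg(mode)
  stopifnot(all(c("member", "year") %in% names(global_events)),
            all(c("scope", "member", "year") %in% names(regional_flags)))
  if ("moderate" %in% names(regional_flags)) {
    regional_flags <- regional_flags[regional_flags$moderate, ]
  }
  regions <- regions %||% sort(unique(regional_flags$scope))
  highlight <- intersect(highlight, regions)
  ge <- global_events[global_events$year >= period[1] & global_events$year <= period[2], ]
  categories <- c("0 regions", paste(highlight, "only"), "Rest only",
                  paste(2:max(2, length(regions)), "regions"))
  if (nrow(ge) == 0) {
    out <- tibble::tibble(category = character(), n_events = integer(),
                          fraction = numeric(), mode = character())
    attr(out, "n_global_events") <- 0L
    attr(out, "status") <- "no-global-events"
    class(out) <- c("coincidence_table", class(out))
    return(out)
  }
  key <- paste(regional_flags$member, regional_flags$year)
  flag_regions <- split(regional_flags$scope, key)
  cats <- vapply(seq_len(nrow(ge)), function(i) {
    rs <- flag_regions[[paste(ge$member[i], ge$year[i])]]
    k <- length(unique(rs))
    if (k == 0) "0 regions"
    else if (k == 1) {
      r <- unique(rs)
      if (r %in% highlight) paste(r, "only") else "Rest only"
    } else paste(k, "regions")
  }, character(1))
  counts <- table(factor(cats, levels = categories))
  out <- tibble::tibble(category = names(counts),
                        n_events = as.integer(counts),
                        fraction = 100 * as.numeric(counts) / nrow(ge),
                        mode = mode)
  attr(out, "n_global_events") <- nrow(ge)
  class(out) <- c("coincidence_table", class(out))
  out
}

#' @export
print.coincidence_table <- function(x, ...) {
  if (identical(attr(x, "status"), "no-global-events")) {
    cat("<coincidence_table> no global record-shattering events in the analysis period\n")
    return(invisible(x))
  }
  cat(sprintf("<coincidence_table> %d global events\n", attr(x, "n_global_events")))
  NextMethod()
}

#' Regional record-shattering events near global events
#'
#' Fraction of global record-shattering events that have at least one
#' regional record-shattering event in the same member within `half_window`
#' years before or after the global event year. Global events are restricted
#' to a period whose full window fits inside the study span (2000-2085 by
#' default for a record ending 2099-2100).
#'
#' @param global_events Global [record_events()] table.
#' @param regional_events Regional [record_events()] table (column `scope`).
#' @param half_window Years before/after (default 15).
#' @param period Inclusive period global events are drawn from.
#' @param regions Region names to report (default: those in
#'   `regional_events`).
#' @return Tibble `region`, `n_global_events`, `n_associated`, `fraction`
#'   (in `[0, 1]`).
#' @export
windowed_association <- function(global_events, regional_events,
                                 half_window = 15, period = c(2000, 2085),
                                 regions = NULL) {
  regions <- regions %||% sort(unique(regional_events$scope))
  ge <- global_events[global_events$year >= period[1] & global_events$year <= period[2], ]
  purrr::map_dfr(regions, function(rn) {
    re <- regional_events[regional_events$scope == rn, ]
    hit <- vapply(seq_len(nrow(ge)), function(i) {
      yrs <- re$year[re$member == ge$member[i]]
      any(abs(yrs - ge$year[i]) <= half_window)
    }, logical(1))
    tibble::tibble(region = rn, n_global_events = nrow(ge),
                   n_associated = sum(hit),
                   fraction = if (nrow(ge)) mean(hit) else NA_real_)
  })
}
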