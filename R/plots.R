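#' Plot drought-area series
#'
#' Member spaghetti with the ensemble mean overlaid, one panel per scope.
#'
#' @param area_tbl A [drought_area()] tibble.
#' @param alpha Member line transparency.
#' @return A ggplot object.
#' @export
plot_area_series <- function(area_tbl, alpha = 0.15) {
  ens <- area_tbl |>
    dplyr::group_by(.data$scope, .data$year) |>
    dplyr::summarise(area = mean(.data$area), .groups = "drop")
  ggplot2::ggplot(area_tbl, ggplot2::aes(.data$year, .data$area)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$member), alpha = alpha,
                       colour = "steelblue") +
    ggplot2::geom_line(data = ens, colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = "Year", y = "Drought area (%)") +
    ggplot2::theme_minimal()
}

#' Plot moving-window record-shattering probability curves
#'
#' @param prob_tbl An [annual_probability()] tibble, optionally with an
#'   `experiment` column (one line per experiment).
#' @return A ggplot object.
#' @export
plot_probability_curve <- function(prob_tbl) {
  p <- ggplot2::ggplot(prob_tbl, ggplot2::aes(.data$year, .data$probability))
  if ("experiment" %in% names(prob_tbl)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$experiment))
  } else {
    p <- p + ggplot2::geom_line(colour = "firebrick")
  }
  p + ggplot2::labs(x = "Window center year",
                    y = "Annual record-shattering probability") +
    ggplot2::theme_minimal()
}

#' Plot regional trend contributions
#'
#' Bars of the multi-model mean contribution of each region's soil-moisture
#' trend to the at-least-one probability, with inter-model range error bars
#' when `min_contribution`/`max_contribution` are present.
#'
#' @param contrib_tbl A contributions summary tibble (see
#'   [run_full_analysis()]) or a [regional_contributions()] result.
#' @return A ggplot object.
#' @export
plot_contributions <- function(contrib_tbl) {
  ycol <- if ("mean_contribution" %in% names(contrib_tbl)) "mean_contribution" else "contribution"
  p <- ggplot2::ggplot(contrib_tbl,
                       ggplot2::aes(.data$region, .data[[ycol]])) +
    ggplot2::geom_col(fill = "steelblue")
  if (all(c("min_contribution", "max_contribution") %in% names(contrib_tbl))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$min_contribution, ymax = .data$max_contribution),
      width = 0.2)
  }
  if ("period" %in% names(contrib_tbl)) p <- p + ggplot2::facet_wrap(~period)
  p + ggplot2::labs(x = NULL, y = "Contribution to P(at least one event)") +
    ggplot2::theme_minimal()
}

#' Plot a coincidence table
#'
#' @param object A `coincidence_table` (or multi-model average).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coincidence_table
#' @export
autoplot.coincidence_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$category, .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "Fraction of global events (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
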