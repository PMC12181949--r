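#' Plot person-day exposure shares by smoke stratum
#'
#' Bar chart of the fraction of person-days of exposure falling in each
#' smoke stratum, optionally comparing several sources.
#'
#' @param ... one or more `person_days_table`s.
#' @return a ggplot object.
#' @export
plot_person_days <- function(...) {
  tab <- dplyr::bind_rows(lapply(list(...), tibble::as_tibble))
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$stratum, y = .data$fraction_of_source_total,
    fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "smoke stratum (ug/m3)",
                  y = "share of person-days of exposure", fill = "source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot strata-specific daily attributable burden rates
#'
#' Dot-and-bar display of mean daily aPM2.5-attributed cardiorespiratory
#' burden rates per 100,000 by smoke stratum, grouped by fire type or
#' scenario.
#'
#' @param ... one or more `strata_burden_table`s.
#' @return a ggplot object.
#' @export
plot_burden_rates <- function(...) {
  tab <- dplyr::bind_rows(lapply(list(...), tibble::as_tibble))
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$stratum, y = .data$daily_rate_per_100k, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "smoke stratum (ug/m3)",
                  y = "attributable visits per 100,000 per day",
                  fill = "fire type / scenario") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scenario comparison
#'
#' Scatter of per-ZIP annual prescribed-fire-attributed burden rates,
#' future versus historical, with the identity line; points above the
#' line are ZIPs whose burden increases under the future scenario.
#'
#' @param object a `scenario_result` from [difference_in_difference()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$historical_rate, y = .data$future_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "historical annual prescribed-fire-attributed rate (per 100,000)",
      y = "future annual prescribed-fire-attributed rate (per 100,000)") +
    ggplot2::theme_minimal()
}
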