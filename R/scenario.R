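#' Zero-smoke counterfactual daily burden rates
#'
#' The counterfactual burden a ZIP would carry with no smoke present is
#' its mean daily aPM2.5-attributed cardiorespiratory rate (per 100,000)
#' over its zero-smoke days (fire type `none`). ZIPs with no zero-smoke
#' days fall back to the statewide rate (mean of the per-ZIP means).
#'
#' @param ledger a historical `burden_ledger`.
#' @return a tibble `zip_id`, `zero_rate`, `n_days` covering every ZIP in
#'   the ledger (fallback rows have `n_days = 0`), with the statewide rate
#'   in the `statewide` attribute.
#' @export
zero_smoke_rates <- function(ledger) {
  if (!nrow(ledger)) abort("empty ledger.")
  day <- cardioresp_by_day(ledger)
  zero <- day |>
    dplyr::filter(.data$fire_type == "none") |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::summarise(
      zero_rate = mean(.data$attributable_count / .data$population * 1e5),
      n_days = dplyr::n(), .groups = "drop")
  if (!nrow(zero)) abort("no zero-smoke days anywhere in the ledger.")
  statewide <- mean(zero$zero_rate)
  out <- dplyr::distinct(day, .data$zip_id) |>
    dplyr::left_join(zero, by = "zip_id") |>
    dplyr::mutate(
      zero_rate = dplyr::coalesce(.data$zero_rate, statewide),
      n_days = dplyr::coalesce(.data$n_days, 0L))
  attr(out, "statewide") <- statewide
  out
}

#' @rdname zero_smoke_rates
#' @param zip_id a single ZIP id.
#' @return `zero_smoke_rate()`: that ZIP's rate (statewide fallback when
#'   it has no zero-smoke days).
#' @export
zero_smoke_rate <- function(ledger, zip_id) {
  rates <- zero_smoke_rates(ledger)
  hit <- rates$zero_rate[rates$zip_id == zip_id]
  if (length(hit)) hit else attr(rates, "statewide")
}

#' Annual prescribed-fire-attributed burden rate per ZIP
#'
#' For each ZIP, sums over its prescribed-fire-impacted days the
#' difference between the aPM2.5-attributed visits and the zero-smoke
#' counterfactual expectation (`zero_rate * population / 1e5`), divides by
#' the population, multiplies by 100,000, and divides by the number of
#' years (historical) or cycles (future). Negative day-level differences
#' are retained so the estimator stays unbiased.
#'
#' @param ledger a historical `burden_ledger` or a future ledger from
#'   [project_future_burden()].
#' @param n_periods number of years (historical) or cycles (future).
#' @param zero_rates output of [zero_smoke_rates()] on the historical
#'   ledger; computed from `ledger` itself when `NULL` (historical only).
#' @param scenario `"historical"` or `"future"`.
#' @param include_both historical only: count days impacted by both
#'   wildfire and prescribed fire as prescribed-fire-impacted (default);
#'   `FALSE` restricts to prescribed-fire-only days.
#' @return an `annual_burden` tibble: `zip_id`, `scenario`,
#'   `rx_attributed_annual_rate` (visits per 100,000 per year),
#'   `n_rx_days`.
#' @export
rx_attributed_annual_rate <- function(ledger, n_periods, zero_rates = NULL,
                                      scenario = c("historical", "future"),
                                      include_both = TRUE) {
  scenario <- match.arg(scenario)
  if (!nrow(ledger)) abort("empty ledger.")
  if (n_periods < 1) abort("n_periods must be >= 1.")
  day <- cardioresp_by_day(ledger)
  if (scenario == "historical") {
    if (is.null(zero_rates)) zero_rates <- zero_smoke_rates(ledger)
    keep <- c("prescribed", if (include_both) "both")
    rx_days <- dplyr::filter(day, .data$fire_type %in% keep)
  } else {
    if (is.null(zero_rates)) {
      abort("future scenario needs `zero_rates` from the historical ledger.")
    }
    rx_days <- day
  }
  all_zips <- dplyr::distinct(day, .data$zip_id, .data$population)
  out <- rx_days |>
    dplyr::left_join(zero_rates[c("zip_id", "zero_rate")], by = "zip_id") |>
    dplyr::mutate(zero_rate = dplyr::coalesce(.data$zero_rate,
                                              attr(zero_rates, "statewide"))) |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::summarise(
      rx_attributed_annual_rate =
        sum(.data$attributable_count -
              .data$zero_rate * .data$population / 1e5) /
        .data$population[1] * 1e5 / n_periods,
      n_rx_days = dplyr::n(), .groups = "drop")
  out <- all_zips["zip_id"] |>
    dplyr::left_join(out, by = "zip_id") |>
    dplyr::mutate(
      scenario = scenario,
      rx_attributed_annual_rate = dplyr::coalesce(.data$rx_attributed_annual_rate, 0),
      n_rx_days = dplyr::coalesce(.data$n_rx_days, 0L)) |>
    dplyr::select("zip_id", "scenario", "rx_attributed_annual_rate", "n_rx_days")
  class(out) <- c("annual_burden", class(out))
  out
}

#' Historical-versus-future difference in prescribed-fire burden
#'
#' Joins per-ZIP annual prescribed-fire-attributed burden rates of the two
#' scenarios and computes `future - historical` for each ZIP (the
#' difference-in-difference of the smoke-attributed burden). A ZIP present
#' in only one scenario contributes 0 for the other and is flagged.
#'
#' @param hist,future `annual_burden` tibbles from
#'   [rx_attributed_annual_rate()].
#' @return a `scenario_result` tibble: `zip_id`, `historical_rate`,
#'   `future_rate`, `difference`, `in_both`.
#' @export
difference_in_difference <- function(hist, future) {
  if (!length(intersect(hist$zip_id, future$zip_id))) {
    abort("the historical and future ZIP sets do not overlap.")
  }
  out <- dplyr::full_join(
    dplyr::select(hist, "zip_id", historical_rate = "rx_attributed_annual_rate"),
    dplyr::select(future, "zip_id", future_rate = "rx_attributed_annual_rate"),
    by = "zip_id") |>
    dplyr::mutate(
      in_both = !is.na(.data$historical_rate) & !is.na(.data$future_rate),
      historical_rate = dplyr::coalesce(.data$historical_rate, 0),
      future_rate = dplyr::coalesce(.data$future_rate, 0),
      difference = .data$future_rate - .data$historical_rate) |>
    dplyr::arrange(.data$zip_id)
  class(out) <- c("scenario_result", class(out))
  out
}

#' Recast a historical panel's prescribed-fire days as a scenario panel
#'
#' Convenience for self-projection checks and sensitivity analyses: the
#' panel's prescribed-fire-impacted ZIP-days become scenario smoke days
#' (one cycle per calendar year, `frx_pm = rx_pm`).
#'
#' @param panel a ZIP-day panel.
#' @param scheme a [strata_scheme()].
#' @return a `scenario_panel` tibble.
#' @export
scenario_from_panel <- function(panel, scheme = strata_scheme()) {
  years <- sort(unique(format(panel$date, "%Y")))
  out <- panel |>
    dplyr::filter(stratum_lower(assign_stratum(.data$rx_pm, scheme)) > 0) |>
    dplyr::mutate(cycle = match(format(.data$date, "%Y"), years)) |>
    dplyr::select("zip_id", "cycle", "date", frx_pm = "rx_pm")
  class(out) <- c("scenario_panel", class(out))
  out
}
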