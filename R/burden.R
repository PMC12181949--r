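#' Expected excess visits attributable to PM2.5
#'
#' Standard excess form used in burden assessment:
#' `observed * (1 - exp(-sum_l beta_l * conc_{t-l}))`, the observed count
#' times the attributable fraction implied by the fitted log relative
#' risks. A linearized variant `observed * sum_l beta_l * conc_{t-l}` is
#' available for sensitivity comparison.
#'
#' @param observed nonnegative observed counts (vector).
#' @param beta log relative risk per ug/m3, one value per lag.
#' @param conc concentrations (ug/m3): a vector (single lag) or a matrix
#'   with one column per lag, rows matching `observed`.
#' @param form `"excess"` (default) or `"linear"`.
#' @return expected excess visits (may be fractional).
#' @examples
#' attributable_visits(100, log(1.0227) / 10, 10)
#' @export
attributable_visits <- function(observed, beta, conc, form = c("excess", "linear")) {
  form <- match.arg(form)
  if (any(!is.finite(beta))) abort("`beta` must be finite.")
  if (any(observed < 0)) abort("`observed` must be nonnegative.")
  conc <- as.matrix(conc)
  if (ncol(conc) != length(beta)) {
    abort("`conc` must have one column per element of `beta`.")
  }
  load <- drop(conc %*% beta)
  af <- switch(form, excess = 1 - exp(-load), linear = load)
  observed * af
}

# lag matrix for attribution: leading days (lag predates series) padded
# with the ZIP's first observed concentration
attribution_lag_matrix <- function(x, zip, lags) {
  first_val <- stats::ave(x, zip, FUN = function(v) v[1])
  m <- vapply(lags, function(l) {
    xl <- shift_within_zip(x, zip, l)
    ifelse(is.na(xl), first_val, xl)
  }, numeric(length(x)))
  colnames(m) <- paste0("apm_lag", lags)
  m
}

#' Attribute ED visits to aPM2.5 per ZIP-day
#'
#' Applies the fitted health impact functions to the panel's aPM2.5
#' series and observed counts, producing a ledger of attributable visits
#' per ZIP-day and outcome, labeled with fire type and with the wildfire
#' and prescribed-fire smoke strata. Each outcome uses its own fitted lag
#' structure (the respiratory attributable fraction distributes the
#' cumulative effect across the fitted per-lag coefficients). Days whose
#' lags predate the series use the ZIP's first concentration as the
#' lag value.
#'
#' @param panel a validated ZIP-day panel.
#' @param hif_resp,hif_cardio fitted [fit_hif()] objects for the
#'   respiratory and cardiovascular outcomes.
#' @param scheme a [strata_scheme()].
#' @return a `burden_ledger` tibble: `zip_id`, `date`, `outcome`,
#'   `observed_count`, `attributable_count`, `fire_type`, `wf_stratum`,
#'   `rx_stratum`, `population`.
#' @export
build_ledger <- function(panel, hif_resp, hif_cardio, scheme = strata_scheme()) {
  stopifnot(inherits(hif_resp, "hif"), inherits(hif_cardio, "hif"))
  if (hif_resp$outcome != "respiratory" || hif_cardio$outcome != "cardiovascular") {
    abort("hif_resp / hif_cardio must be fitted for respiratory / cardiovascular.")
  }
  panel <- dplyr::arrange(panel, .data$zip_id, .data$date)
  fire_type <- classify_fire_type(panel$wf_pm, panel$rx_pm, scheme)
  wf_stratum <- assign_stratum(panel$wf_pm, scheme)
  rx_stratum <- assign_stratum(panel$rx_pm, scheme)

  one_outcome <- function(hif, y) {
    lags <- seq(hif$lag_window[1], hif$lag_window[2])
    cm <- attribution_lag_matrix(panel$apm, panel$zip_id, lags)
    tibble::tibble(
      zip_id = panel$zip_id, date = panel$date, outcome = hif$outcome,
      observed_count = y,
      attributable_count = attributable_visits(y, hif$lag_coefficients, cm),
      fire_type = fire_type, wf_stratum = wf_stratum, rx_stratum = rx_stratum,
      population = panel$population
    )
  }
  out <- dplyr::bind_rows(
    one_outcome(hif_resp, panel$resp_count),
    one_outcome(hif_cardio, panel$cardio_count)
  )
  attr(out, "scheme") <- scheme
  class(out) <- c("burden_ledger", class(out))
  out
}

# cardiorespiratory (respiratory + cardiovascular) attributable count per
# ZIP-day, carrying the day's labels
cardioresp_by_day <- function(ledger) {
  grouping <- intersect(
    c("zip_id", "cycle", "date", "fire_type", "wf_stratum", "rx_stratum",
      "frx_stratum", "population"),
    names(ledger))
  ledger |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(attributable_count = sum(.data$attributable_count),
                     .groups = "drop")
}

#' Strata-specific daily attributable burden rates
#'
#' Computes statewide strata-specific aPM2.5 burden rates for
#' cardiorespiratory (respiratory + cardiovascular) attributable visits in
#' three steps: (1) for each ZIP and smoke stratum, sum the attributable
#' visits and divide by the number of days in the stratum (average daily
#' incidence); (2) divide by the ZIP population and multiply by 100,000;
#' (3) average these daily rates, unweighted, across all ZIPs with at
#' least one day in the stratum. Strata with no days are omitted.
#'
#' @param ledger a `burden_ledger` (historical, from [build_ledger()]) or
#'   a future ledger from [project_future_burden()].
#' @param fire which stratification to tabulate: `"wildfire"` /
#'   `"prescribed"` bin days by that source's own smoke concentration
#'   (non-zero strata); `"none"` is the zero-smoke stratum (days impacted
#'   by neither source); `"future"` bins a future ledger by its fRx
#'   stratum.
#' @return a `strata_burden_table` tibble: `group`, `stratum`,
#'   `daily_rate_per_100k`, `n_zip_days`, `n_zips`.
#' @export
strata_burden_rates <- function(ledger,
                                fire = c("wildfire", "prescribed", "none", "future")) {
  fire <- match.arg(fire)
  if (!nrow(ledger)) abort("empty ledger.")
  day <- cardioresp_by_day(ledger)
  day <- switch(fire,
    wildfire = dplyr::mutate(
      dplyr::filter(day, stratum_lower(.data$wf_stratum) > 0),
      stratum = .data$wf_stratum),
    prescribed = dplyr::mutate(
      dplyr::filter(day, stratum_lower(.data$rx_stratum) > 0),
      stratum = .data$rx_stratum),
    none = dplyr::mutate(
      dplyr::filter(day, .data$fire_type == "none"),
      stratum = .data$wf_stratum),
    future = dplyr::mutate(day, stratum = .data$frx_stratum)
  )
  out <- day |>
    dplyr::group_by(.data$zip_id, .data$stratum) |>
    dplyr::summarise(
      zip_rate = sum(.data$attributable_count) / dplyr::n() /
        .data$population[1] * 1e5,
      n_days = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      group = fire,
      daily_rate_per_100k = mean(.data$zip_rate),
      n_zip_days = sum(.data$n_days),
      n_zips = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("group") |>
    dplyr::arrange(.data$stratum)
  class(out) <- c("strata_burden_table", class(out))
  out
}

#' Project historical burden rates onto the future scenario
#'
#' Assigns to each projected prescribed-fire smoke ZIP-day the historical
#' aPM2.5-attributed cardiorespiratory burden rate of the same ZIP,
#' matched by day of the year (mean across historical years; February 29
#' maps to February 28), and converts it to an attributable count via the
#' ZIP population. Scenario ZIPs absent from the historical ledger are
#' excluded with a warning.
#'
#' @param ledger historical `burden_ledger`.
#' @param scenario a `scenario_panel` from [generate_future_scenario()].
#' @param scheme a [strata_scheme()].
#' @return a future `burden_ledger` tibble: `zip_id`, `cycle`, `date`,
#'   `frx_pm`, `frx_stratum`, `attributable_count`, `population`.
#' @export
project_future_burden <- function(ledger, scenario, scheme = strata_scheme()) {
  day <- cardioresp_by_day(ledger) |>
    dplyr::mutate(rate = .data$attributable_count / .data$population * 1e5,
                  mmdd = mmdd_of(.data$date))
  profile <- day |>
    dplyr::group_by(.data$zip_id, .data$mmdd) |>
    dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  pops <- dplyr::distinct(day, .data$zip_id, .data$population)
  missing <- setdiff(unique(scenario$zip_id), pops$zip_id)
  if (length(missing)) {
    warn(sprintf("%d scenario ZIP(s) absent from the historical ledger; excluded.",
                 length(missing)))
  }
  out <- scenario |>
    dplyr::filter(!.data$zip_id %in% missing) |>
    dplyr::mutate(mmdd = mmdd_of(.data$date)) |>
    dplyr::inner_join(profile, by = c("zip_id", "mmdd")) |>
    dplyr::inner_join(pops, by = "zip_id") |>
    dplyr::mutate(
      frx_stratum = assign_stratum(.data$frx_pm, scheme),
      attributable_count = .data$rate * .data$population / 1e5
    ) |>
    dplyr::select("zip_id", "cycle", "date", "frx_pm", "frx_stratum",
                  "attributable_count", "population")
  attr(out, "scheme") <- scheme
  class(out) <- c("burden_ledger_future", class(out))
  out
}

mmdd_of <- function(date) {
  x <- format(date, "%m-%d")
  x[x == "02-29"] <- "02-28"
  x
}
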