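panel_columns <- c("zip_id", "date", "population", "apm", "wf_pm", "rx_pm",
                   "temp", "rh", "resp_count", "cardio_count")

#' Read and write ZIP-day panels as CSV
#'
#' Panels travel as RFC-4180 CSV with ISO-8601 dates. `write_panel()` can
#' drop a sidecar `<path>.meta` file (plain `key: value` lines) recording
#' the generator configuration and seed for reproducibility.
#'
#' @param panel a ZIP-day panel tibble.
#' @param path CSV file path.
#' @param config optional [generator_config()] recorded in the sidecar.
#' @return `write_panel()` returns `path` invisibly; `read_panel()`
#'   returns a tibble (unvalidated; see [validate_panel()]).
#' @export
write_panel <- function(panel, path, config = NULL) {
  readr::write_csv(panel, path)
  if (!is.null(config)) {
    vals <- vapply(config, function(v) paste(format(v, digits = 17), collapse = " "),
                   character(1))
    writeLines(paste0(names(config), ": ", vals), paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(
      zip_id = readr::col_character(),
      date = readr::col_date(format = "")
    ))
}

#' Validate a ZIP-day panel
#'
#' Enforces the panel contract before modelling: required columns, parsed
#' dates, no duplicate (ZIP, date) keys, nonnegative concentrations,
#' nonnegative integer counts, population constant within ZIP, and the
#' low-population exclusion rule (default threshold 1,500 persons,
#' dropped with a message).
#'
#' @param x a data frame or a CSV path.
#' @param min_pop population exclusion threshold.
#' @return a validated `zip_day_panel` tibble, ZIP-days sorted.
#' @export
validate_panel <- function(x, min_pop = 1500) {
  panel <- if (is.character(x)) read_panel(x) else tibble::as_tibble(x)
  missing <- setdiff(panel_columns, names(panel))
  if (length(missing)) {
    abort(paste0("missing panel columns: ", paste(missing, collapse = ", ")))
  }
  if (!inherits(panel$date, "Date")) {
    panel$date <- as.Date(panel$date)
  }
  if (any(is.na(panel$date))) abort("unparseable dates in panel.")
  dup <- panel |>
    dplyr::count(.data$zip_id, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate (zip_id, date) keys, e.g. (%s, %s).",
                  dup$zip_id[1], format(dup$date[1])))
  }
  for (col in c("apm", "wf_pm", "rx_pm")) {
    if (any(!is.finite(panel[[col]])) || any(panel[[col]] < 0)) {
      abort(sprintf("column `%s` must be finite and nonnegative.", col))
    }
  }
  for (col in c("resp_count", "cardio_count")) {
    v <- panel[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != as.integer(v))) {
      abort(sprintf("column `%s` must contain nonnegative integers.", col))
    }
  }
  pop_var <- panel |>
    dplyr::group_by(.data$zip_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$population) == 1L)
  if (!all(pop_var$ok)) {
    abort("population must be constant within each ZIP.")
  }
  panel <- dplyr::arrange(panel, .data$zip_id, .data$date)
  out <- apply_population_filter(panel, min_pop)
  class(out) <- unique(c("zip_day_panel", class(out)))
  out
}

#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: the synthetic generator
#' configuration (or a pre-built panel), the strata scheme, candidate lag
#' windows per outcome, the confounder specification, the population
#' exclusion threshold, and the future-scenario settings.
#'
#' @param generator a [generator_config()]; ignored when `panel` is given.
#' @param panel optional pre-built ZIP-day panel (tibble or CSV path).
#' @param scheme a [strata_scheme()].
#' @param lag_candidates named list with elements `respiratory` and
#'   `cardiovascular`, each a list of candidate lag windows for BIC
#'   selection; a window like `c(0, 4)` skips selection.
#' @param confounders a [confounder_spec()].
#' @param min_pop population exclusion threshold.
#' @param n_cycles future-scenario annual cycles.
#' @param burn_days_per_zip see [generate_future_scenario()].
#' @param run_scenario include the future-scenario stages.
#' @param out_dir optional directory for CSV artifacts.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            panel = NULL,
                            scheme = strata_scheme(),
                            lag_candidates = list(
                              respiratory = list(c(0L, 0L), c(0L, 4L)),
                              cardiovascular = list(c(0L, 0L), c(0L, 4L))),
                            confounders = confounder_spec(),
                            min_pop = 1500,
                            n_cycles = 8L,
                            burn_days_per_zip = 40,
                            run_scenario = TRUE,
                            out_dir = NULL) {
  structure(list(generator = generator, panel = panel, scheme = scheme,
                 lag_candidates = lag_candidates, confounders = confounders,
                 min_pop = min_pop, n_cycles = n_cycles,
                 burn_days_per_zip = burn_days_per_zip,
                 run_scenario = run_scenario, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full smoke-burden pipeline
#'
#' Executes the stages in order: simulate (unless a panel is supplied) ->
#' validate -> fit the two health impact functions (with BIC lag window
#' selection) -> attribute visits into a burden ledger -> person-day
#' exposure tables -> project the future prescribed-fire scenario ->
#' annual prescribed-fire-attributed rates and their per-ZIP difference.
#' The run is deterministic given the generator seed.
#'
#' @param config a [pipeline_config()].
#' @return a named list (`panel`, `hif_respiratory`, `hif_cardiovascular`,
#'   `ledger`, `exposure_tables`, `burden_tables`, `scenario`,
#'   `future_ledger`, `annual_historical`, `annual_future`, `result`,
#'   `manifest`), with CSV artifacts under `out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }
  panel <- stage("simulate", {
    if (is.null(config$panel)) generate_panel(config$generator) else config$panel
  })
  panel <- stage("validate", validate_panel(panel, config$min_pop))
  n_years <- length(unique(format(panel$date, "%Y")))

  fit_one <- function(outcome) stage(paste0("fit-", outcome), {
    cands <- config$lag_candidates[[outcome]]
    if (!is.list(cands)) cands <- list(cands)
    win <- if (length(cands) > 1) {
      select_lag_window(panel, outcome, cands, config$confounders)
    } else cands[[1]]
    fits <- attr(win, "fits")
    if (!is.null(fits)) {
      fits[[which(vapply(fits, function(f)
        !is.null(f) && identical(f$lag_window, as.integer(win)), logical(1)))[1]]]
    } else {
      fit_hif(panel, outcome, win, config$confounders)
    }
  })
  hif_resp <- fit_one("respiratory")
  hif_cardio <- fit_one("cardiovascular")

  ledger <- stage("attribute",
                  build_ledger(panel, hif_resp, hif_cardio, config$scheme))
  exposure_tables <- stage("exposure", {
    tabs <- lapply(c(apm = "apm", wf = "wf", rx = "rx"), function(s) {
      person_days_table(panel, config$scheme, s, annualize_by = n_years)
    })
    tabs
  })
  burden_tables <- stage("burden-rates", list(
    none = strata_burden_rates(ledger, "none"),
    wildfire = strata_burden_rates(ledger, "wildfire"),
    prescribed = strata_burden_rates(ledger, "prescribed")
  ))

  scenario <- future_ledger <- annual_future <- result <- NULL
  annual_hist <- stage("annual-historical",
                       rx_attributed_annual_rate(ledger, n_periods = n_years))
  if (isTRUE(config$run_scenario)) {
    scenario <- stage("scenario", generate_future_scenario(
      config$generator, config$n_cycles, config$burn_days_per_zip,
      zip_ids = unique(panel$zip_id)))
    future_ledger <- stage("project",
                           project_future_burden(ledger, scenario, config$scheme))
    burden_tables$future <- stage("burden-rates-future",
                                  strata_burden_rates(future_ledger, "future"))
    zr <- zero_smoke_rates(ledger)
    annual_future <- stage("annual-future", rx_attributed_annual_rate(
      future_ledger, n_periods = config$n_cycles, zero_rates = zr,
      scenario = "future"))
    result <- stage("compare", difference_in_difference(annual_hist, annual_future))
    pops <- dplyr::distinct(panel, .data$zip_id, .data$population)
    exposure_tables$frx <- stage("exposure-frx", person_days_table(
      dplyr::inner_join(scenario, pops, by = "zip_id"),
      config$scheme, "frx", annualize_by = config$n_cycles))
  }
  manifest <- list(
    seed = config$generator$seed,
    n_zips = length(unique(panel$zip_id)),
    date_range = range(panel$date),
    n_years = n_years,
    n_cycles = if (isTRUE(config$run_scenario)) config$n_cycles else NA_integer_,
    lag_respiratory = hif_resp$lag_window,
    lag_cardiovascular = hif_cardio$lag_window,
    package_version = as.character(utils::packageVersion("smokeburden"))
  )
  bundle <- list(panel = panel, hif_respiratory = hif_resp,
                 hif_cardiovascular = hif_cardio, ledger = ledger,
                 exposure_tables = exposure_tables,
                 burden_tables = burden_tables,
                 scenario = scenario, future_ledger = future_ledger,
                 annual_historical = annual_hist, annual_future = annual_future,
                 result = result, manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(bundle$panel, file.path(out_dir, "panel.csv"))
  readr::write_csv(dplyr::bind_rows(lapply(bundle$exposure_tables, tibble::as_tibble)),
                   file.path(out_dir, "person_days.csv"))
  readr::write_csv(dplyr::bind_rows(lapply(bundle$burden_tables, tibble::as_tibble)),
                   file.path(out_dir, "strata_burden_rates.csv"))
  readr::write_csv(dplyr::bind_rows(
    glance(bundle$hif_respiratory), glance(bundle$hif_cardiovascular)),
    file.path(out_dir, "health_impact_functions.csv"))
  readr::write_csv(bundle$ledger, file.path(out_dir, "burden_ledger.csv"))
  if (!is.null(bundle$result)) {
    readr::write_csv(bundle$result, file.path(out_dir, "scenario_result.csv"))
  }
  vals <- vapply(bundle$manifest, function(v) paste(format(v), collapse = " "),
                 character(1))
  writeLines(paste0(names(bundle$manifest), ": ", vals),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
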