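#' Person-day exposure accounting by smoke stratum
#'
#' For one exposure source, counts the ZIP-days whose concentration bins
#' to each stratum and accumulates the exposed population
#' (person-days = sum of ZIP population over qualifying ZIP-days). This is
#' the per-source analog of published annual smoke exposure tables.
#'
#' @param data a data frame with `population` and the source's
#'   concentration column (`apm`, `wf_pm`, `rx_pm` or `frx_pm`). For a
#'   future-scenario panel, join ZIP populations on first.
#' @param scheme a [strata_scheme()].
#' @param source one of `"apm"`, `"wf"`, `"rx"`, `"frx"`.
#' @param annualize_by divide ZIP-day and person-day totals by this number
#'   of years (historical) or cycles (future); `NULL` leaves pooled totals.
#' @param include_zero keep the zero stratum as a row. Fractions are always
#'   computed over non-zero (smoke) strata, matching the convention of
#'   reporting shares of smoke-day exposure.
#' @return a `person_days_table` tibble with columns `source`, `stratum`,
#'   `zip_days`, `person_days`, `fraction_of_source_total`.
#' @examples
#' cfg <- generator_config(n_zips = 3, end_date = "2008-03-31")
#' person_days_table(generate_panel(cfg), source = "rx")
#' @export
person_days_table <- function(data, scheme = strata_scheme(),
                              source = c("apm", "wf", "rx", "frx"),
                              annualize_by = NULL, include_zero = FALSE) {
  source <- match.arg(source)
  col <- c(apm = "apm", wf = "wf_pm", rx = "rx_pm", frx = "frx_pm")[[source]]
  if (!col %in% names(data)) {
    abort(sprintf("column `%s` (source %s) not found in `data`.", col, source))
  }
  empty <- tibble::tibble(
    source = source, stratum = factor(scheme$label, scheme$label, ordered = TRUE),
    zip_days = 0, person_days = 0, fraction_of_source_total = 0
  )
  if (!nrow(data)) {
    out <- if (include_zero) empty else empty[-1, ]
    class(out) <- c("person_days_table", class(out))
    return(out)
  }
  tab <- data |>
    dplyr::mutate(stratum = assign_stratum(.data[[col]], scheme)) |>
    dplyr::group_by(.data$stratum, .drop = FALSE) |>
    dplyr::summarise(zip_days = dplyr::n(),
                     person_days = sum(as.numeric(.data$population)),
                     .groups = "drop") |>
    dplyr::mutate(source = source, .before = 1)
  smoke <- tab$stratum != scheme$label[1]
  tot <- sum(tab$person_days[smoke])
  tab$fraction_of_source_total <-
    ifelse(smoke, if (tot > 0) tab$person_days / tot else 0, NA_real_)
  if (!include_zero) tab <- tab[smoke, ]
  if (!is.null(annualize_by)) {
    tab$zip_days <- tab$zip_days / annualize_by
    tab$person_days <- tab$person_days / annualize_by
  }
  class(tab) <- c("person_days_table", class(tab))
  tab
}

#' Fold ratio of person-day exposure between two sources
#'
#' Ratio of summed person-days over a subset of strata, e.g. future
#' prescribed fire versus historical prescribed fire. Both tables must be
#' on the same annualization.
#'
#' @param table_a,table_b `person_days_table`s (numerator, denominator).
#' @param strata character vector of stratum labels to sum over; `NULL`
#'   uses every stratum present.
#' @param above alternative to `strata`: sum only strata whose lower bound
#'   exceeds this concentration (ug/m3).
#' @return a single fold-ratio number.
#' @export
exposure_ratio <- function(table_a, table_b, strata = NULL, above = NULL) {
  pick <- function(tab) {
    lab <- as.character(tab$stratum)
    sel <- rep(TRUE, nrow(tab))
    if (!is.null(strata)) sel <- lab %in% strata
    if (!is.null(above)) sel <- sel & stratum_lower(lab) > above
    sum(tab$person_days[sel])
  }
  den <- pick(table_b)
  if (den <= 0) abort("denominator person-days are zero over the selected strata.")
  pick(table_a) / den
}

#' Lower concentration bound parsed from stratum labels
#'
#' @param labels character stratum labels such as `"5.01-10.00"`,
#'   `"150.01+"` or `"0"`.
#' @return numeric lower bounds (ug/m3).
#' @export
stratum_lower <- function(labels) {
  as.numeric(sub("^([0-9.]+).*$", "\\1", as.character(labels)))
}

#' Packaged annual smoke exposure reference table
#'
#' Loads the packaged reference table of annual ZIP-days and person-days
#' of exposure by smoke stratum for four sources: total ambient PM2.5
#' (`apm`), historical prescribed fire (`rx`), historical wildfire (`wf`),
#' and the future prescribed-fire scenario (`frx`). Historical columns are
#' annual averages over 2008--2016; the future column is averaged over the
#' scenario's eight annual cycles. Person-days are stored in millions as
#' printed (`person_days_m`) alongside the printed percentage share
#' (`printed_pct`); `person_days` is the same quantity in raw person-days.
#'
#' @param source optionally restrict to one source, returning a
#'   `person_days_table` usable with [exposure_ratio()].
#' @return a tibble (all sources, long) or a `person_days_table`.
#' @examples
#' reference_person_days("rx")
#' @export
reference_person_days <- function(source = NULL) {
  path <- system.file("extdata", "person_days_reference.csv",
                      package = "smokeburden", mustWork = TRUE)
  wide <- readr::read_csv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(
    wide, -"stratum",
    names_to = c("source", ".value"),
    names_pattern = "^(apm|rx|wf|frx)_(.*)$"
  ) |>
    dplyr::rename(printed_pct = "pct", person_days_m = "person_days_m") |>
    dplyr::mutate(
      stratum = factor(.data$stratum, unique(wide$stratum), ordered = TRUE),
      person_days = .data$person_days_m * 1e6
    )
  if (is.null(source)) return(long)
  src <- match.arg(source, c("apm", "rx", "wf", "frx"))
  out <- long |>
    dplyr::filter(.data$source == src) |>
    dplyr::mutate(
      fraction_of_source_total = .data$person_days / sum(.data$person_days)
    ) |>
    dplyr::select("source", "stratum", "zip_days", "person_days",
                  "fraction_of_source_total", "printed_pct")
  class(out) <- c("person_days_table", class(out))
  out
}
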