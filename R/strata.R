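#' Smoke concentration strata scheme
#'
#' The analysis classifies each ZIP-day's smoke PM2.5 concentration into
#' ordered strata. Concentrations are first rounded to a fixed precision
#' (default two decimals, half away from zero), so the closed intervals
#' below form an exact partition of the nonnegative reals: a value that
#' rounds to 0.00 falls in the distinguished zero stratum, and every other
#' rounded value falls in exactly one bin.
#'
#' The default scheme uses the bins
#' `0; 0.01-0.05; 0.06-0.10; 0.11-0.25; 0.26-0.50; 0.51-1.00; 1.01-5.00;
#' 5.01-10.00; 10.01-15.00; 15.01-20.00; 20.01-50.00; 50.01-100.00;
#' 100.01-150.00; 150.01+` (ug/m3). `collapse_top = TRUE` merges the three
#' top bins into a single `50.01+` stratum, the layout used in published
#' person-day exposure tables whose historical maximum concentration was
#' 1120 ug/m3.
#'
#' @param collapse_top collapse all strata above 50.00 ug/m3 into one.
#' @param precision decimal places used when rounding before binning.
#' @return A tibble of class `strata_scheme` with columns `label`, `lower`,
#'   `upper` (ug/m3; `Inf` for the open top bin) ordered by concentration.
#'   The zero stratum is the first row with `lower = upper = 0`.
#' @examples
#' strata_scheme()
#' @export
strata_scheme <- function(collapse_top = FALSE, precision = 2L) {
  lower <- c(0, 0.01, 0.06, 0.11, 0.26, 0.51, 1.01, 5.01, 10.01, 15.01,
             20.01, 50.01, 100.01, 150.01)
  upper <- c(0, 0.05, 0.10, 0.25, 0.50, 1.00, 5.00, 10.00, 15.00, 20.00,
             50.00, 100.00, 150.00, Inf)
  if (collapse_top) {
    keep <- lower < 50.005
    lower <- c(lower[keep], 50.01)
    upper <- c(upper[keep], Inf)
  }
  fmt <- function(x) formatC(x, format = "f", digits = precision)
  label <- ifelse(
    lower == 0, "0",
    ifelse(is.infinite(upper), paste0(fmt(lower), "+"),
           paste0(fmt(lower), "-", fmt(upper)))
  )
  out <- tibble::tibble(label = label, lower = lower, upper = upper)
  attr(out, "precision") <- as.integer(precision)
  class(out) <- c("strata_scheme", class(out))
  out
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; strata binning requires the
#' conventional half-away-from-zero rule so that, e.g., 0.005 bins upward.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # epsilon guards decimal halves that sit just under .5 in binary
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# integer "cents" representation of stratum lower bounds, for exact matching
.scheme_lower_int <- function(scheme) {
  p <- 10^(attr(scheme, "precision") %||% 2L)
  as.integer(round(scheme$lower * p))
}

#' Assign smoke concentrations to strata
#'
#' Rounds each concentration to the scheme's precision (half away from
#' zero) and returns the label of the unique stratum whose closed bounds
#' contain the rounded value.
#'
#' @param conc numeric vector of concentrations (ug/m3), finite and >= 0.
#' @param scheme a [strata_scheme()].
#' @return factor of stratum labels with levels ordered by concentration.
#' @examples
#' assign_stratum(c(0.004, 0.07, 3.2, 1120))
#' @export
assign_stratum <- function(conc, scheme = strata_scheme()) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    abort("`conc` must be finite and nonnegative.")
  }
  prec <- attr(scheme, "precision") %||% 2L
  p <- 10^prec
  cents <- as.integer(round(round_half_up(conc, prec) * p))
  idx <- findInterval(cents, .scheme_lower_int(scheme))
  factor(scheme$label[idx], levels = scheme$label, ordered = TRUE)
}

#' Classify a ZIP-day by fire type
#'
#' A ZIP-day is impacted by wildfire, prescribed fire, both, or neither,
#' according to whether each smoke concentration bins to the zero stratum.
#'
#' @param wf_pm,rx_pm wildfire and prescribed-fire smoke PM2.5 (ug/m3).
#' @param scheme a [strata_scheme()].
#' @return factor with levels `none`, `wildfire`, `prescribed`, `both`.
#' @examples
#' classify_fire_type(c(0, 3.2, 0, 3.2), c(0, 0, 0.4, 0.4))
#' @export
classify_fire_type <- function(wf_pm, rx_pm, scheme = strata_scheme()) {
  wf0 <- assign_stratum(wf_pm, scheme) == scheme$label[1]
  rx0 <- assign_stratum(rx_pm, scheme) == scheme$label[1]
  out <- dplyr::case_when(
    wf0 & rx0 ~ "none",
    !wf0 & rx0 ~ "wildfire",
    wf0 & !rx0 ~ "prescribed",
    TRUE ~ "both"
  )
  factor(out, levels = c("none", "wildfire", "prescribed", "both"))
}

#' @export
print.strata_scheme <- function(x, ...) {
  cat("<strata_scheme> ", nrow(x), " strata (ug/m3)\n", sep = "")
  NextMethod()
}
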