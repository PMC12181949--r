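#' Configuration for the synthetic ZIP-day panel generator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the package is calibrated to:
#' a California-like state of ~1,300 ZIP codes observed daily over
#' 2008--2016, ambient all-source PM2.5 (aPM2.5) averaging 9.11 ug/m3 with
#' winter-peaking seasonality, episodic wildfire smoke peaking June to
#' September, episodic prescribed-fire smoke peaking November to January,
#' baseline emergency-department (ED) visit rates of 11.5 (respiratory) and
#' 12.6 (cardiovascular) per 100,000 persons per day, and log-linear
#' concentration-response truths of 2.27% (respiratory, distributed over
#' lags 0--4) and 0.89% (cardiovascular, same day) per 10 ug/m3 aPM2.5.
#'
#' @param n_zips number of ZIP codes.
#' @param start_date,end_date panel date range (coerced with `as.Date`).
#' @param population_range min/max ZIP population (uniform draw; the
#'   default minimum equals the 1,500-person exclusion threshold so default
#'   panels contain no excludable ZIPs; set a lower minimum to exercise the
#'   exclusion rule).
#' @param baseline_resp_rate,baseline_cardio_rate baseline ED visit rates,
#'   visits per 100,000 persons per day.
#' @param ambient_mean,ambient_sd mean and day-to-day standard deviation of
#'   the seasonal ambient PM2.5 background (ug/m3).
#' @param seasonal_amplitude amplitude of the annual ambient PM2.5 cycle
#'   (ug/m3), peaking mid-January.
#' @param wf_event_rate,rx_event_rate smoke events per ZIP-year for
#'   wildfire and prescribed fire.
#' @param wf_intensity_logmean,wf_intensity_logsd lognormal parameters of
#'   wildfire event peak concentrations (log ug/m3).
#' @param rx_intensity_logmean,rx_intensity_logsd lognormal parameters of
#'   prescribed-fire event peak concentrations.
#' @param wf_intensity_max,rx_intensity_max upper truncation of event peak
#'   concentrations (ug/m3), matching the maximum smoke concentrations
#'   observed historically (1120 wildfire, 253 prescribed fire); keeps the
#'   log-linear response within its supported range.
#' @param frx_intensity_logmean,frx_intensity_logsd lognormal parameters of
#'   future-scenario prescribed-fire day concentrations; the default puts
#'   over 99% of the mass below 5 ug/m3.
#' @param wf_duration_mean,rx_duration_mean mean event duration in days
#'   (geometric).
#' @param smoke_decay per-day geometric decay factor of event
#'   concentrations after the peak.
#' @param true_resp_pct_per10,true_cardio_pct_per10 injected percent change
#'   in ED visits per 10 ug/m3 aPM2.5. Respiratory acts through the
#'   lag-weighted exposure, cardiovascular through same-day exposure.
#' @param resp_lag_weights five nonnegative weights over lags 0--4 summing
#'   to 1 that distribute the respiratory truth across lags.
#' @param zip_intercept_sd standard deviation of ZIP-level log-rate
#'   intercepts (mean is offset by -sd^2/2 so expected rates match the
#'   baselines).
#' @param confounder_effects named numeric: log-rate slopes of `temp`
#'   (per degree C from 15) and `rh` (per percentage point from 60).
#' @param count_season_amplitude amplitude of the annual log-rate cycle of
#'   counts not explained by PM or confounders.
#' @param dow_effects length-7 log-rate offsets, Sunday first.
#' @param nb_size if non-`NULL`, counts are negative binomial with this
#'   size (overdispersion robustness switch); default Poisson.
#' @param seed master integer seed; per-ZIP substreams are derived from it
#'   so adding ZIPs does not perturb existing ones.
#' @return a validated list of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_zips = 5, end_date = "2008-06-30")
#' @export
generator_config <- function(n_zips = 1297L,
                             start_date = "2008-01-01",
                             end_date = "2016-12-31",
                             population_range = c(1500, 105000),
                             baseline_resp_rate = 11.5,
                             baseline_cardio_rate = 12.6,
                             ambient_mean = 9.11,
                             ambient_sd = 6.0,
                             seasonal_amplitude = 2.5,
                             wf_event_rate = 8,
                             rx_event_rate = 10,
                             wf_intensity_logmean = log(8),
                             wf_intensity_logsd = 1.4,
                             rx_intensity_logmean = 0,
                             rx_intensity_logsd = 1.2,
                             wf_intensity_max = 1120,
                             rx_intensity_max = 253,
                             frx_intensity_logmean = log(0.3),
                             frx_intensity_logsd = 1.1,
                             wf_duration_mean = 4,
                             rx_duration_mean = 2,
                             smoke_decay = 0.6,
                             true_resp_pct_per10 = 2.27,
                             true_cardio_pct_per10 = 0.89,
                             resp_lag_weights = rep(0.2, 5),
                             zip_intercept_sd = 0.15,
                             confounder_effects = c(temp = 0.002, rh = -0.001),
                             count_season_amplitude = 0.05,
                             dow_effects = c(0.03, 0, -0.01, -0.01, -0.01, 0, 0.02),
                             nb_size = NULL,
                             seed = 1L) {
  cfg <- list(
    n_zips = as.integer(n_zips),
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    population_range = as.numeric(population_range),
    baseline_resp_rate = baseline_resp_rate,
    baseline_cardio_rate = baseline_cardio_rate,
    ambient_mean = ambient_mean, ambient_sd = ambient_sd,
    seasonal_amplitude = seasonal_amplitude,
    wf_event_rate = wf_event_rate, rx_event_rate = rx_event_rate,
    wf_intensity_logmean = wf_intensity_logmean,
    wf_intensity_logsd = wf_intensity_logsd,
    rx_intensity_logmean = rx_intensity_logmean,
    rx_intensity_logsd = rx_intensity_logsd,
    wf_intensity_max = wf_intensity_max,
    rx_intensity_max = rx_intensity_max,
    frx_intensity_logmean = frx_intensity_logmean,
    frx_intensity_logsd = frx_intensity_logsd,
    wf_duration_mean = wf_duration_mean,
    rx_duration_mean = rx_duration_mean,
    smoke_decay = smoke_decay,
    true_resp_pct_per10 = true_resp_pct_per10,
    true_cardio_pct_per10 = true_cardio_pct_per10,
    resp_lag_weights = as.numeric(resp_lag_weights),
    zip_intercept_sd = zip_intercept_sd,
    confounder_effects = confounder_effects,
    count_season_amplitude = count_season_amplitude,
    dow_effects = as.numeric(dow_effects),
    nb_size = nb_size,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  num <- unlist(cfg[!(names(cfg) %in% c("start_date", "end_date", "nb_size"))])
  if (any(!is.finite(num))) abort("generator config contains non-finite values.")
  if (is.na(cfg$start_date) || is.na(cfg$end_date)) {
    abort("start_date and end_date must be valid dates.")
  }
  if (cfg$end_date <= cfg$start_date) abort("end_date must be after start_date.")
  nonneg <- c("baseline_resp_rate", "baseline_cardio_rate", "ambient_mean",
              "ambient_sd", "seasonal_amplitude", "wf_event_rate",
              "rx_event_rate", "wf_duration_mean", "rx_duration_mean",
              "zip_intercept_sd")
  bad <- nonneg[vapply(nonneg, function(f) cfg[[f]] < 0, logical(1))]
  if (length(bad)) abort(paste0("negative value for: ", paste(bad, collapse = ", ")))
  if (cfg$n_zips < 1L) abort("n_zips must be >= 1.")
  if (length(cfg$population_range) != 2 || cfg$population_range[1] < 1 ||
      diff(cfg$population_range) < 0) {
    abort("population_range must be an increasing pair with minimum >= 1.")
  }
  w <- cfg$resp_lag_weights
  if (length(w) != 5 || any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    abort("resp_lag_weights must be 5 nonnegative weights summing to 1.")
  }
  if (length(cfg$dow_effects) != 7) abort("dow_effects must have length 7.")
  n_days <- as.integer(cfg$end_date - cfg$start_date) + 1L
  if (n_days < length(w)) {
    abort("date range shorter than the maximum lag plus one day.")
  }
  invisible(cfg)
}

# deterministic per-(zip, stream) substream seed below 2^31
zip_substream_seed <- function(seed, i, stream = 0L) {
  (abs(as.numeric(seed)) %% 1e6) * 2011 + i * 7919 + stream * 104729
}

# episodic smoke series: block events with lognormal peak and geometric decay
smoke_series <- function(n_days, doy, rate_per_year, logmean, logsd,
                         duration_mean, decay, peak_doy, peak_max = Inf) {
  out <- numeric(n_days)
  n_events <- rpois(1L, rate_per_year * n_days / 365.25)
  if (n_events == 0L) return(out)
  w <- exp(1.5 * cos(2 * pi * (doy - peak_doy) / 365.25))
  starts <- sample.int(n_days, n_events, replace = TRUE, prob = w)
  durations <- rgeom(n_events, 1 / duration_mean) + 1L
  peaks <- pmin(rlnorm(n_events, logmean, logsd), peak_max)
  for (e in seq_len(n_events)) {
    idx <- starts[e]:min(n_days, starts[e] + durations[e] - 1L)
    out[idx] <- out[idx] + peaks[e] * decay^(seq_along(idx) - 1L)
  }
  out
}

# lag-weighted exposure, leading days padded with the first observation
lag_weighted <- function(x, weights) {
  out <- numeric(length(x))
  for (l in seq_along(weights) - 1L) {
    xl <- c(rep(x[1], l), head(x, length(x) - l))
    out <- out + weights[l + 1L] * xl
  }
  out
}

#' Generate a synthetic historical ZIP-day panel
#'
#' Simulates daily ZIP-level records of population, ambient PM2.5,
#' wildfire and prescribed-fire smoke PM2.5, temperature, relative
#' humidity, and respiratory / cardiovascular ED visit counts, with the
#' statistical structure the downstream analysis assumes: ambient PM2.5 is
#' a winter-peaking seasonal background (gamma day-to-day noise) plus
#' episodic smoke; counts are Poisson (optionally negative binomial) with
#' log mean equal to `log(baseline * population / 1e5)` plus a ZIP
#' intercept, seasonal and day-of-week terms, linear confounder terms, and
#' the injected concentration-response `beta * exposure` where `beta` per
#' ug/m3 is `log(1 + pct_per10 / 100) / 10`. Respiratory counts respond to
#' the lag-weighted (lags 0--4) aPM2.5, cardiovascular counts to same-day
#' aPM2.5.
#'
#' The generator is deterministic given the config (including its seed),
#' and each ZIP uses its own substream, so increasing `n_zips` leaves
#' previously generated ZIPs unchanged.
#'
#' @param config a [generator_config()].
#' @return a `zip_day_panel` tibble with one row per ZIP-day, columns
#'   `zip_id`, `date`, `population`, `apm`, `wf_pm`, `rx_pm`, `temp`,
#'   `rh`, `resp_count`, `cardio_count`.
#' @examples
#' panel <- generate_panel(generator_config(n_zips = 3, end_date = "2008-03-31"))
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  dates <- seq(config$start_date, config$end_date, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  dow <- as.integer(format(dates, "%w")) + 1L  # Sunday = 1
  beta_r <- log(1 + config$true_resp_pct_per10 / 100) / 10
  beta_c <- log(1 + config$true_cardio_pct_per10 / 100) / 10
  ce <- config$confounder_effects
  season_count <- config$count_season_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  dow_term <- config$dow_effects[dow]

  zips <- vector("list", config$n_zips)
  for (i in seq_len(config$n_zips)) {
    set.seed(zip_substream_seed(config$seed, i))
    pop <- round(runif(1, config$population_range[1], config$population_range[2]))
    zi_r <- rnorm(1, -config$zip_intercept_sd^2 / 2, config$zip_intercept_sd)
    zi_c <- rnorm(1, -config$zip_intercept_sd^2 / 2, config$zip_intercept_sd)

    temp <- 15 + 8 * cos(2 * pi * (doy - 196) / 365.25) + rnorm(n, 0, 3)
    rh <- pmin(100, pmax(5, 60 - 0.8 * (temp - 15) + rnorm(n, 0, 8)))

    m_t <- pmax(0.5, config$ambient_mean +
                  config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25))
    apm_bg <- if (config$ambient_sd > 0) {
      rgamma(n, shape = m_t^2 / config$ambient_sd^2,
             rate = m_t / config$ambient_sd^2)
    } else m_t
    wf_pm <- smoke_series(n, doy, config$wf_event_rate,
                          config$wf_intensity_logmean, config$wf_intensity_logsd,
                          config$wf_duration_mean, config$smoke_decay, 196,
                          config$wf_intensity_max)
    rx_pm <- smoke_series(n, doy, config$rx_event_rate,
                          config$rx_intensity_logmean, config$rx_intensity_logsd,
                          config$rx_duration_mean, config$smoke_decay, 350,
                          config$rx_intensity_max)
    apm <- apm_bg + wf_pm + rx_pm

    x_resp <- lag_weighted(apm, config$resp_lag_weights)
    base_r <- log(pop * config$baseline_resp_rate / 1e5)
    base_c <- log(pop * config$baseline_cardio_rate / 1e5)
    conf <- ce[["temp"]] * (temp - 15) + ce[["rh"]] * (rh - 60)
    mu_r <- exp(base_r + zi_r + season_count + dow_term + conf + beta_r * x_resp)
    mu_c <- exp(base_c + zi_c + season_count + dow_term + conf + beta_c * apm)
    if (is.null(config$nb_size)) {
      resp <- rpois(n, mu_r)
      cardio <- rpois(n, mu_c)
    } else {
      resp <- rnbinom(n, mu = mu_r, size = config$nb_size)
      cardio <- rnbinom(n, mu = mu_c, size = config$nb_size)
    }
    zips[[i]] <- tibble::tibble(
      zip_id = sprintf("Z%04d", i), date = dates, population = pop,
      apm = apm, wf_pm = wf_pm, rx_pm = rx_pm, temp = temp, rh = rh,
      resp_count = resp, cardio_count = cardio
    )
  }
  out <- dplyr::bind_rows(zips)
  class(out) <- c("zip_day_panel", class(out))
  out
}

#' Generate a future prescribed-fire scenario panel
#'
#' Simulates the smoke-day records of a hypothetical expanded
#' prescribed-fire program: each participating ZIP receives, in each of
#' `n_cycles` annual cycles, a seeded random set of burn days within a
#' single representative meteorological year (2014, a non-leap year,
#' reused across cycles), weighted toward November--January. Daily
#' future-prescribed-fire (fRx) concentrations are lognormal and, at the
#' default calibration, over 99% of the mass lies below 5 ug/m3 --
#' low-concentration, high-frequency exposure relative to historical
#' wildfire.
#'
#' @param config a [generator_config()] (supplies intensity parameters,
#'   ZIP ids and the master seed).
#' @param n_cycles number of annual cycles (years) of the program.
#' @param burn_days_per_zip either a single count (every ZIP-cycle gets
#'   exactly that many smoke days) or a list `list(mean = m)` giving a
#'   Poisson mean per ZIP-cycle.
#' @param zip_ids participating ZIPs; default all ZIPs of the config.
#' @return a `scenario_panel` tibble with columns `zip_id`, `cycle`,
#'   `date`, `frx_pm` (one row per projected smoke ZIP-day).
#' @examples
#' cfg <- generator_config(n_zips = 2)
#' sc <- generate_future_scenario(cfg, n_cycles = 2, burn_days_per_zip = 5)
#' @export
generate_future_scenario <- function(config, n_cycles = 8L,
                                     burn_days_per_zip = 40,
                                     zip_ids = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (n_cycles < 1) abort("n_cycles must be >= 1.")
  if (is.null(zip_ids)) zip_ids <- sprintf("Z%04d", seq_len(config$n_zips))
  if (!length(zip_ids)) abort("no participating ZIPs.")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  year_dates <- seq(as.Date("2014-01-01"), as.Date("2014-12-31"), by = "day")
  doy <- seq_along(year_dates)
  w <- exp(2 * cos(2 * pi * (doy - 350) / 365))
  rows <- list()
  for (i in seq_along(zip_ids)) {
    for (cyc in seq_len(n_cycles)) {
      set.seed(zip_substream_seed(config$seed, i, stream = cyc))
      nd <- if (is.list(burn_days_per_zip)) {
        rpois(1L, burn_days_per_zip$mean)
      } else as.integer(burn_days_per_zip)
      nd <- min(nd, length(year_dates))
      if (nd == 0L) next
      days <- sort(sample.int(length(year_dates), nd, prob = w))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        zip_id = zip_ids[i], cycle = cyc, date = year_dates[days],
        frx_pm = rlnorm(nd, config$frx_intensity_logmean,
                        config$frx_intensity_logsd)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scenario_panel", class(out))
  out
}

#' Exclude low-population ZIP codes from a panel
#'
#' Small-population ZIPs are excluded before modelling (default threshold
#' 1,500 persons, the study's model-performance exclusion rule).
#'
#' @param panel a ZIP-day panel.
#' @param min_pop minimum population retained.
#' @return the filtered panel; excluded ZIPs are recorded in the
#'   `excluded_zips` attribute and reported via a message (a warning when
#'   everything is excluded).
#' @export
apply_population_filter <- function(panel, min_pop = 1500) {
  if (min_pop < 0) abort("min_pop must be >= 0.")
  pops <- dplyr::distinct(panel, .data$zip_id, .data$population)
  drop <- pops$zip_id[pops$population < min_pop]
  out <- dplyr::filter(panel, !.data$zip_id %in% drop)
  attr(out, "excluded_zips") <- pops[pops$zip_id %in% drop, ]
  if (length(drop)) {
    inform(sprintf("excluded %d ZIP(s) below population %s",
                   length(drop), format(min_pop, big.mark = ",")))
  }
  if (!nrow(out)) warn("all ZIPs fall below the population threshold; empty panel.")
  out
}
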