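test_that("attributable visits match the closed-form excess formula", {
  beta <- log(1.0227) / 10
  expect_equal(attributable_visits(100, beta, 10),
               100 * (1 - 1 / 1.0227), tolerance = 1e-10)
  expect_equal(attributable_visits(100, 0, 10), 0)
  expect_equal(attributable_visits(100, beta, 0), 0)
  expect_equal(attributable_visits(0, beta, 50), 0)
  # multi-lag form
  b <- rep(beta / 5, 5)
  conc <- matrix(10, 1, 5)
  expect_equal(attributable_visits(100, b, conc),
               100 * (1 - 1 / 1.0227), tolerance = 1e-10)
  # linearized variant exceeds the excess form slightly for beta > 0
  expect_gt(attributable_visits(100, beta, 10, form = "linear"),
            attributable_visits(100, beta, 10))
  expect_error(attributable_visits(100, Inf, 10), "finite")
  expect_error(attributable_visits(-1, beta, 10), "nonnegative")
})

test_that("attributable fraction is bounded and increasing in exposure", {
  beta <- log(1.05) / 10
  conc <- seq(0, 500, by = 25)
  af <- attributable_visits(1, beta, matrix(conc, ncol = 1))
  expect_true(all(af >= 0 & af < 1))
  expect_true(all(diff(af) > 0))
})

fit_small_hifs <- function(p) {
  list(resp = fit_hif(p, "respiratory", c(0, 4)),
       cardio = fit_hif(p, "cardiovascular", c(0, 0)))
}

test_that("the ledger conserves attributable counts and labels every day", {
  p <- generate_panel(tiny_config(seed = 31))
  h <- fit_small_hifs(p)
  led <- build_ledger(p, h$resp, h$cardio)
  expect_equal(nrow(led), 2 * nrow(p))
  expect_true(all(c("fire_type", "wf_stratum", "rx_stratum") %in% names(led)))
  # partition additivity: fire-type sums equal the total
  tot <- sum(led$attributable_count)
  by_type <- tapply(led$attributable_count, led$fire_type, sum)
  expect_equal(sum(by_type, na.rm = TRUE), tot)
  by_stratum <- tapply(led$attributable_count, led$wf_stratum, sum)
  expect_equal(sum(by_stratum, na.rm = TRUE), tot)
  # the excess form can never attribute more than was observed
  expect_true(all(led$attributable_count <= led$observed_count + 1e-12))
})

test_that("a zero-concentration panel attributes nothing", {
  p <- manual_panel(n_days = 20)
  p$apm <- 0
  h <- fit_small_hifs(generate_panel(tiny_config(seed = 32)))
  led <- build_ledger(p, h$resp, h$cardio)
  expect_true(all(led$attributable_count == 0))
})

# hif carrying the generator's true coefficients, bypassing estimation,
# so attribution can be checked against an independent oracle exactly
truth_hif <- function(outcome, pct_per10, weights) {
  beta <- log(1 + pct_per10 / 100) / 10
  structure(list(outcome = outcome,
                 lag_window = c(0L, length(weights) - 1L),
                 lag_coefficients = setNames(
                   beta * weights, paste0("apm_lag", seq_along(weights) - 1L))),
            class = "hif")
}

test_that("ledger totals match an independently computed expectation", {
  cfg <- small_config(seed = 33)
  p <- generate_panel(cfg)
  hr <- truth_hif("respiratory", cfg$true_resp_pct_per10, cfg$resp_lag_weights)
  hc <- truth_hif("cardiovascular", cfg$true_cardio_pct_per10, 1)
  led <- build_ledger(p, hr, hc)
  # oracle: explicit per-ZIP loop over days and lags (leading lags use the
  # first concentration, as documented)
  beta_r <- log(1 + cfg$true_resp_pct_per10 / 100) / 10
  oracle <- sum(unlist(lapply(split(p, p$zip_id), function(z) {
    z <- z[order(z$date), ]
    load <- vapply(seq_len(nrow(z)), function(t) {
      sum(cfg$resp_lag_weights * beta_r * z$apm[pmax(t - 0:4, 1)])
    }, numeric(1))
    z$resp_count * (1 - exp(-load))
  })))
  got <- sum(led$attributable_count[led$outcome == "respiratory"])
  expect_equal(got, oracle, tolerance = 1e-10)
  # and the simple Monte-Carlo sanity bound: totals scale like
  # E[y] * beta * mean exposure
  expect_gt(got, 0)
})

test_that("strata burden rates follow the three-step definition", {
  # one ZIP, pop 50,000: stratum with 4 days totalling 2.0 attributable
  led <- manual_ledger(tibble::tibble(
    zip_id = "A", date = as.Date("2010-01-01") + 0:3,
    outcome = "respiratory", observed_count = 5L,
    attributable_count = 0.5,
    fire_type = factor("wildfire", c("none", "wildfire", "prescribed", "both")),
    wf_stratum = "1.01-5.00", rx_stratum = "0", population = 50000))
  tab <- strata_burden_rates(led, "wildfire")
  expect_equal(tab$daily_rate_per_100k, 2 / 4 / 50000 * 1e5)
  expect_equal(tab$n_zip_days, 4)

  # two ZIPs with per-ZIP rates 1.0 and 3.0 average to 2.0 (unweighted)
  led2 <- manual_ledger(tibble::tibble(
    zip_id = c("A", "B"), date = as.Date("2010-01-01"),
    outcome = "respiratory", observed_count = 5L,
    attributable_count = c(1.0 * 50000 / 1e5, 3.0 * 20000 / 1e5),
    fire_type = factor("wildfire", c("none", "wildfire", "prescribed", "both")),
    wf_stratum = "1.01-5.00", rx_stratum = "0",
    population = c(50000, 20000)))
  tab2 <- strata_burden_rates(led2, "wildfire")
  expect_equal(tab2$daily_rate_per_100k, 2.0)
  expect_equal(tab2$n_zips, 2)
})

test_that("future projection averages the day-of-year rate profile", {
  # 3-year history with a known deterministic per-ZIP seasonal rate profile
  dates <- seq(as.Date("2011-01-01"), as.Date("2013-12-31"), by = "day")
  doy_rate <- function(d, shift) 0.1 + 0.05 * sin(2 * pi * as.integer(
    format(d, "%j")) / 366) + shift
  led <- dplyr::bind_rows(lapply(c(A = 0, B = 0.02), function(s) {
    tibble::tibble(
      zip_id = if (s == 0) "A" else "B", date = dates,
      outcome = "cardiorespiratory", observed_count = 1L,
      attributable_count = doy_rate(dates, s) * 40000 / 1e5,
      fire_type = factor("none", c("none", "wildfire", "prescribed", "both")),
      wf_stratum = "0", rx_stratum = "0", population = 40000)
  }))
  led <- manual_ledger(led)
  sc <- tibble::tibble(zip_id = "A", cycle = 1L,
                       date = as.Date(c("2014-03-01", "2014-11-15")),
                       frx_pm = c(0.3, 2.0))
  fut <- project_future_burden(led, sc)
  expected <- vapply(sc$date, function(d) {
    hist_days <- dates[format(dates, "%m-%d") == format(d, "%m-%d")]
    mean(doy_rate(hist_days, 0)) * 40000 / 1e5
  }, numeric(1))
  expect_equal(fut$attributable_count, expected, tolerance = 1e-12)
  expect_identical(as.character(fut$frx_stratum), c("0.26-0.50", "1.01-5.00"))
  # unknown scenario ZIP excluded with a warning
  sc_bad <- dplyr::mutate(sc, zip_id = "ZZ")
  expect_warning(out <- project_future_burden(led, sc_bad), "absent")
  expect_equal(nrow(out), 0)
})

test_that("single-year history projects its own rates exactly", {
  # non-leap year so every day of year occurs exactly once in history
  p <- generate_panel(generator_config(
    n_zips = 6, start_date = "2009-01-01", end_date = "2009-12-31", seed = 34))
  h <- fit_small_hifs(p)
  led <- build_ledger(p, h$resp, h$cardio)
  day <- smokeburden:::cardioresp_by_day(led)
  sc <- scenario_from_panel(p)
  fut <- project_future_burden(led, sc)
  joined <- dplyr::inner_join(
    dplyr::select(fut, zip_id, date, fut_att = attributable_count),
    dplyr::select(day, zip_id, date, hist_att = attributable_count),
    by = c("zip_id", "date"))
  expect_equal(nrow(joined), nrow(fut))
  expect_equal(joined$fut_att, joined$hist_att, tolerance = 1e-12)
})
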