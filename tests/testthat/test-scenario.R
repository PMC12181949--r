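ft_levels <- c("none", "wildfire", "prescribed", "both")

# ledger with explicit per-day attributable rates (per 100K) for a ZIP set
rate_ledger <- function(zip_id, rates_per_100k, fire_type, pop = 100000,
                        start = as.Date("2012-01-01")) {
  manual_ledger(tibble::tibble(
    zip_id = zip_id,
    date = start + seq_along(rates_per_100k) - 1,
    outcome = "cardiorespiratory", observed_count = 1L,
    attributable_count = rates_per_100k * pop / 1e5,
    fire_type = factor(fire_type, ft_levels),
    wf_stratum = ifelse(fire_type %in% c("wildfire", "both"), "1.01-5.00", "0"),
    rx_stratum = ifelse(fire_type %in% c("prescribed", "both"), "0.01-0.05", "0"),
    population = pop))
}

test_that("zero-smoke rates average the no-smoke days with fallback", {
  led <- dplyr::bind_rows(
    rate_ledger("A", c(0.2, 0.4), c("none", "none")),
    rate_ledger("B", c(0.5, 1.0), c("prescribed", "prescribed")))
  zr <- zero_smoke_rates(led)
  expect_equal(zr$zero_rate[zr$zip_id == "A"], 0.3)
  # B has no zero-smoke days: statewide fallback (here the mean over ZIPs
  # that have them, i.e. A's 0.3)
  expect_equal(zr$zero_rate[zr$zip_id == "B"], 0.3)
  expect_equal(zero_smoke_rate(led, "B"), 0.3)
  expect_equal(attr(zr, "statewide"), 0.3)
  led_all_smoke <- rate_ledger("A", c(1, 2), c("wildfire", "wildfire"))
  expect_error(zero_smoke_rates(led_all_smoke), "no zero-smoke")
})

test_that("annual prescribed-fire-attributed rate follows the counterfactual arithmetic", {
  # one Rx day with 2.0 attributable visits, zero-smoke expectation 1.0,
  # pop 100,000, one year -> 1.0 per 100K per year
  led <- dplyr::bind_rows(
    rate_ledger("A", 1.0, "none"),
    rate_ledger("A", 2.0, "prescribed", start = as.Date("2012-06-01")))
  ab <- rx_attributed_annual_rate(led, n_periods = 1)
  expect_equal(ab$rx_attributed_annual_rate, 1.0)
  expect_equal(ab$n_rx_days, 1L)
  # a ZIP with no Rx-impacted days reports zero
  led2 <- dplyr::bind_rows(led, rate_ledger("B", c(0.2, 0.2), c("none", "none")))
  ab2 <- rx_attributed_annual_rate(led2, n_periods = 1)
  expect_equal(ab2$rx_attributed_annual_rate[ab2$zip_id == "B"], 0)
  # restricting to Rx-only days drops 'both' days
  led3 <- dplyr::bind_rows(led, rate_ledger("A", 5.0, "both",
                                            start = as.Date("2012-09-01")))
  with_both <- rx_attributed_annual_rate(led3, n_periods = 1)
  rx_only <- rx_attributed_annual_rate(led3, n_periods = 1, include_both = FALSE)
  expect_gt(with_both$rx_attributed_annual_rate[with_both$zip_id == "A"],
            rx_only$rx_attributed_annual_rate[rx_only$zip_id == "A"])
  expect_equal(rx_only$rx_attributed_annual_rate[rx_only$zip_id == "A"], 1.0)
})

test_that("difference in difference subtracts per ZIP with flags", {
  hist <- rx_attributed_annual_rate(
    dplyr::bind_rows(rate_ledger("A", 1.0, "none"),
                     rate_ledger("A", 11, "prescribed",
                                 start = as.Date("2012-03-01"))),
    n_periods = 1)
  fut <- hist
  fut$scenario <- "future"
  fut$rx_attributed_annual_rate <- 30
  hist$rx_attributed_annual_rate <- 10
  res <- difference_in_difference(hist, fut)
  expect_equal(res$difference, 20)
  # identical scenarios give all zeros
  same <- difference_in_difference(hist, hist)
  expect_true(all(same$difference == 0))
  # disjoint ZIP sets error
  fut2 <- dplyr::mutate(fut, zip_id = "Q")
  expect_error(difference_in_difference(hist, fut2), "overlap")
})

test_that("scaling Rx exposure days scales the attributed difference linearly", {
  # future scenario with 15x the Rx smoke days at equal per-day excess
  zero_days <- rate_ledger("A", rep(0.5, 10), rep("none", 10))
  one_rx <- rate_ledger("A", 1.5, "prescribed", start = as.Date("2012-08-01"))
  hist_led <- dplyr::bind_rows(zero_days, one_rx)
  hist <- rx_attributed_annual_rate(hist_led, n_periods = 1)
  # replicate the Rx day 15 times on distinct days
  many_rx <- dplyr::bind_rows(lapply(1:15, function(i)
    rate_ledger("A", 1.5, "prescribed", start = as.Date("2012-08-01") + i)))
  fut_led <- dplyr::bind_rows(zero_days, many_rx)
  fut <- rx_attributed_annual_rate(fut_led, n_periods = 1)
  fut$scenario <- "future"
  res <- difference_in_difference(hist, fut)
  expect_equal(res$difference, 14 * hist$rx_attributed_annual_rate,
               tolerance = 1e-12)
})

test_that("self-projection of the historical period nulls the difference", {
  # non-leap year: day-of-year matching is then a bijection
  p <- generate_panel(generator_config(
    n_zips = 6, start_date = "2009-01-01", end_date = "2009-12-31", seed = 35))
  hr <- fit_hif(p, "respiratory", c(0, 4))
  hc <- fit_hif(p, "cardiovascular", c(0, 0))
  led <- build_ledger(p, hr, hc)
  zr <- zero_smoke_rates(led)
  hist <- rx_attributed_annual_rate(led, n_periods = 1, zero_rates = zr)
  sc <- scenario_from_panel(p)
  fut_led <- project_future_burden(led, sc)
  fut <- rx_attributed_annual_rate(fut_led, n_periods = 1, zero_rates = zr,
                                   scenario = "future")
  res <- difference_in_difference(hist, fut)
  expect_lt(max(abs(res$difference)), 1e-10)
})

test_that("adding positive-excess Rx days increases the annual rate", {
  base <- dplyr::bind_rows(
    rate_ledger("A", rep(0.5, 5), rep("none", 5)),
    rate_ledger("A", 1.0, "prescribed", start = as.Date("2012-07-01")))
  more <- dplyr::bind_rows(
    base, rate_ledger("A", 1.2, "prescribed", start = as.Date("2012-10-01")))
  r_base <- rx_attributed_annual_rate(base, n_periods = 1)
  r_more <- rx_attributed_annual_rate(more, n_periods = 1)
  expect_gt(r_more$rx_attributed_annual_rate, r_base$rx_attributed_annual_rate)
})
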