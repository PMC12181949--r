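# small configurations shared across tests; sizes chosen to keep the
# default suite fast while leaving enough events in every stratum

tiny_config <- function(seed = 1, ...) {
  generator_config(n_zips = 6, start_date = "2008-01-01",
                   end_date = "2008-12-31", seed = seed, ...)
}

small_config <- function(seed = 1, ...) {
  generator_config(n_zips = 20, start_date = "2008-01-01",
                   end_date = "2009-12-31", seed = seed, ...)
}

# deterministic hand-built panel for arithmetic oracles
manual_panel <- function(zips = c("A", "B"), pops = c(50000, 80000),
                         n_days = 10, start = as.Date("2010-01-01")) {
  dplyr::bind_rows(lapply(seq_along(zips), function(i) {
    tibble::tibble(
      zip_id = zips[i],
      date = seq(start, by = "day", length.out = n_days),
      population = pops[i],
      apm = 10, wf_pm = 0, rx_pm = 0, temp = 15, rh = 60,
      resp_count = 1L, cardio_count = 1L
    )
  }))
}

# ledger with fully controlled attribution values for scenario arithmetic
manual_ledger <- function(df) {
  need <- c("zip_id", "date", "outcome", "observed_count",
            "attributable_count", "fire_type", "wf_stratum", "rx_stratum",
            "population")
  out <- tibble::as_tibble(df)
  stopifnot(all(need %in% names(out)))
  class(out) <- c("burden_ledger", class(out))
  out
}
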