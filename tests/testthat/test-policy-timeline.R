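test_that("wolf-year bounds follow exact calendar arithmetic", {
  wy <- wolf_year_bounds(2003)
  expect_equal(wy$start, as.Date("2002-04-15"))
  expect_equal(wy$end, as.Date("2003-04-14"))
  expect_equal(wy$n_days, 365L)

  # leap-day year: the 1996 wolf-year contains 29 Feb 1996
  expect_equal(wolf_year_bounds(1996)$n_days, 366L)

  # independent calendar oracle over a span of years
  for (t in 1990:2015) {
    wy <- wolf_year_bounds(t)
    oracle <- length(seq(as.Date(sprintf("%d-04-15", t - 1)),
                         as.Date(sprintf("%d-04-14", t)), by = "day"))
    expect_equal(wy$n_days, oracle)
  }
})

test_that("consecutive wolf-years partition the calendar without gap or overlap", {
  bounds <- wolf_year_bounds(1995:2012)
  expect_true(all(diff(bounds$start) == diff(bounds$end + 1) |
                    bounds$start[-1] == bounds$end[-nrow(bounds)] + 1))
  expect_true(all(bounds$start[-1] == bounds$end[-nrow(bounds)] + 1))
  # total days covered equals the span of the union
  expect_equal(sum(bounds$n_days),
               as.integer(bounds$end[nrow(bounds)] - bounds$start[1]) + 1L)
})

test_that("signal covariate counts inclusive days of allowed periods", {
  periods <- tibble::tibble(
    state = "WI",
    start = as.Date("2003-04-01"),
    end = as.Date("2003-04-14"),
    culling_allowed = TRUE
  )
  sig <- compute_signal(periods, 2003, "WI")
  expect_equal(sig$days_allowed, 14L)
  expect_equal(sig$D, 14 / 365)

  # full coverage gives exactly 1
  full <- tibble::tibble(state = "WI", start = as.Date("2002-04-15"),
                         end = as.Date("2003-04-14"), culling_allowed = TRUE)
  expect_equal(compute_signal(full, 2003, "WI")$D, 1)

  # no allowed periods gives exactly 0, and disallowed periods are ignored
  off <- dplyr::mutate(full, culling_allowed = FALSE)
  expect_equal(compute_signal(off, 2003, "WI")$D, 0)
  expect_equal(compute_signal(full[0, ], 2003, "WI")$D, 0)
})

test_that("periods are clipped to the wolf-year and never double-counted", {
  # one period straddling two wolf-years
  periods <- tibble::tibble(state = "WI", start = as.Date("2003-03-01"),
                            end = as.Date("2003-05-15"), culling_allowed = TRUE)
  s3 <- compute_signal(periods, 2003, "WI")
  s4 <- compute_signal(periods, 2004, "WI")
  total <- as.integer(as.Date("2003-05-15") - as.Date("2003-03-01")) + 1L
  expect_equal(s3$days_allowed + s4$days_allowed, total)

  # D invariant under splitting into abutting sub-periods
  split_periods <- tibble::tibble(
    state = "WI",
    start = as.Date(c("2003-03-01", "2003-04-20")),
    end = as.Date(c("2003-04-19", "2003-05-15")),
    culling_allowed = TRUE
  )
  expect_equal(compute_signal(split_periods, 2003, "WI")$D, s3$D)
  expect_equal(compute_signal(split_periods, 2004, "WI")$D, s4$D)
})

test_that("overlapping periods within a state are rejected, naming the pair", {
  periods <- tibble::tibble(
    state = c("WI", "WI"),
    start = as.Date(c("2003-01-01", "2003-02-01")),
    end = as.Date(c("2003-03-01", "2003-04-01")),
    culling_allowed = TRUE
  )
  expect_error(validate_policy_periods(periods), "overlapping.*2003-01-01.*2003-02-01")
  # same dates in different states are fine
  periods$state <- c("WI", "MI")
  expect_silent(validate_policy_periods(periods))
  # start after end
  bad <- tibble::tibble(state = "WI", start = as.Date("2003-05-01"),
                        end = as.Date("2003-04-01"), culling_allowed = TRUE)
  expect_error(validate_policy_periods(bad), "start after end")
})

test_that("signal table round-trips through CSV and covers all state-years", {
  periods <- default_policy_periods()
  sig <- signal_covariates(periods, 1995:2012)
  expect_equal(nrow(sig), 2 * 18)
  expect_true(all(sig$D >= 0 & sig$D <= 1))
  expect_true(all(sig$D[sig$wolf_year < 2003] == 0))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_signal_covariates(sig, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(back$D, sig$D)

  ptmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(periods, ptmp)
  expect_equal(read_policy_periods(ptmp)$start, periods$start)
})
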