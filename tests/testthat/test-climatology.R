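tz <- "Etc/GMT-10"

test_that("site extremes reduce grids exactly", {
  tms <- hourly_times("2001-01-01 00:00:00", 2)
  uniform <- matrix(12, 4, 4)
  hot <- uniform; hot[2, 3] <- 30
  ex <- site_extremes(list(uniform, hot), tms)
  expect_equal(ex$utci_max, c(12, 30))
  expect_equal(ex$utci_min, c(12, 12))
  expect_error(site_extremes(list(matrix(NA_real_, 2, 2)), tms[1]), "missing")
})

test_that("change fields reproduce exact arithmetic on constructed members", {
  tms_h <- hourly_times("2001-01-01 00:00:00", 8760)
  tms_f <- hourly_times("2051-01-01 00:00:00", 8760)
  base <- sin(seq_along(tms_h) / 500)
  h1 <- data.frame(time = tms_h, tair = base)
  f1 <- data.frame(time = tms_f, tair = base + 1)
  h2 <- h1
  f2 <- data.frame(time = tms_f, tair = base + 3)

  mean_f <- change_by_hour_doy(list(h1, h2), list(f1, f2), "mean")
  sd_f <- change_by_hour_doy(list(h1, h2), list(f1, f2), "sd")
  expect_equal(dim(mean_f), c(24, 365))
  expect_true(all(abs(mean_f - 2) < 1e-12))
  expect_true(all(abs(sd_f - sqrt(2)) < 1e-12))
  hm <- attr(mean_f, "hour_month")
  expect_equal(dim(hm), c(24, 12))
  expect_true(all(abs(hm - 2) < 1e-12))

  uniform <- change_by_hour_doy(list(h1), list(f1), "mean")
  expect_true(all(abs(uniform - 1) < 1e-12))
  expect_error(change_by_hour_doy(list(h1), list(f1), "sd"), "members")
})

test_that("future medians as historic percentiles hit the analytic anchors", {
  tms_h <- hourly_times("2001-01-01 00:00:00", 4 * 8760)
  tms_f <- hourly_times("2051-01-01 00:00:00", 4 * 8760)
  set.seed(8)
  x <- rnorm(length(tms_h))
  hist <- data.frame(time = tms_h, tair = x)
  # identical distribution -> 50th percentile (per-group medians interpolate)
  same <- median_as_historic_percentile(hist, data.frame(time = tms_f, tair = x))
  expect_lt(abs(mean(same) - 50), 2)
  # shift above every historic value -> 100
  up <- median_as_historic_percentile(hist,
                                      data.frame(time = tms_f, tair = x + 50))
  expect_true(all(up == 100))
})

test_that("a +1 SD normal shift sits near the 84th percentile at large n", {
  set.seed(12)
  hv <- rnorm(20000)
  expect_lt(abs(heatscape:::percentile_rank(hv, 1) - 100 * pnorm(1)), 2)
})

test_that("percentile bands per hour: constants, robustness and order statistics", {
  tms <- hourly_times("2001-01-01 00:00:00", 24 * 200)
  const <- data.frame(time = tms, utci_max = rep(7, length(tms)))
  b <- percentile_bands_by_hour(const)
  expect_true(all(b$p5 == 7 & b$p50 == 7 & b$p95 == 7))

  set.seed(3)
  u <- runif(length(tms))
  bu <- percentile_bands_by_hour(data.frame(time = tms, utci_max = u))
  expect_lt(max(abs(bu$p95 - 0.95)), 0.05)
  # symmetric contamination leaves the median unchanged
  x <- rep(10, 100); x[1:10] <- 0; x[11:20] <- 20
  expect_equal(median(x), 10)
})

test_that("stress-hour tables count constructed flags exactly", {
  tms <- hourly_times("2001-01-01 00:00:00", 2 * 8760)
  lt <- as.POSIXlt(tms)
  flags <- lt$hour == 14 & lt$mon == 0      # every January day, 14:00, 2 years
  sh <- stress_hours(tms, flags)
  expect_equal(unname(sh$by_hour["14"]), 31)
  expect_equal(unname(sh$by_month["Jan"]), 31)
  expect_equal(sum(sh$by_hour != 0), 1)
  expect_equal(sum(sh$by_month != 0), 1)
  expect_equal(sh$annual_total, 31)
  # month totals and hour totals agree with the annual total
  expect_equal(sum(sh$by_month), sh$annual_total)
  expect_equal(sum(sh$by_hour), sh$annual_total)

  none <- stress_hours(tms, rep(FALSE, length(tms)))
  expect_true(all(none$by_month == 0) && all(none$by_hour == 0))
})

test_that("scope nesting: site-wide stress implies any-cell stress", {
  set.seed(6)
  n <- 500
  ex <- data.frame(time = hourly_times("2001-01-01 00:00:00", n),
                   utci_min = runif(n, -15, 25))
  ex$utci_max <- ex$utci_min + runif(n, 0, 15)
  for (rollup in c("heat", "cold", "no_stress")) {
    site <- stress_flags(ex, rollup, "site_wide")
    any_ <- stress_flags(ex, rollup, "any_cell")
    expect_true(all(!site | any_))
  }
})

test_that("June-May spans accumulate and date first occurrences correctly", {
  tms <- hourly_times("2001-06-01 00:00:00", 2 * 8760)
  flags <- rep(FALSE, length(tms))
  hit1 <- which(format(tms, "%Y-%m-%d %H") == "2001-10-10 15")
  flags[hit1] <- TRUE
  # 23:00 on 31 May 2002 belongs to the span that began June 2001
  hit2 <- which(format(tms, "%Y-%m-%d %H") == "2002-05-31 23")
  flags[hit2] <- TRUE
  rec <- cumulative_stress_june_may(tms, flags)
  expect_equal(rec$span_start_year, c(2001, 2002))
  expect_equal(rec$total, c(2, 0))
  expect_equal(format(rec$first_occurrence[1], "%Y-%m-%d"), "2001-10-10")
  expect_true(is.na(rec$first_occurrence[2]))
  cum <- attr(rec, "cumulative")[["2001"]]
  expect_true(all(diff(cum) >= 0))
  expect_equal(tail(cum, 1), 2)
  expect_error(cumulative_stress_june_may(tms[1:100], flags[1:100]), "span")
})

test_that("summary table: identical periods give zero change and unit factors", {
  tms <- hourly_times("2001-01-01 00:00:00", 8760)
  met <- flat_met(tms, tair = 15, rh = 60, wind = 3, swdown = 0)
  set.seed(2)
  ex <- data.frame(time = tms, utci_min = runif(8760, -10, 20))
  ex$utci_max <- ex$utci_min + 8
  tab <- summary_table(met, met, ex, ex)
  expect_true(all(tab$means$net_change == 0))
  cf <- tab$stress$change_factor
  expect_true(all(cf[!is.na(cf)] == 1))
})

test_that("net changes and change factors reproduce a published summary's arithmetic", {
  # Hobart ensemble summary, 1990-2005 vs 2040-2059 (printed period entries)
  expect_equal(summary_arithmetic(12.1, 13.5)$net_change, 1.4)
  expect_equal(summary_arithmetic(7.6, 9.4)$net_change, 1.8)
  expect_equal(summary_arithmetic(154.5, 159.2)$net_change, 4.7)
  expect_equal(summary_arithmetic(hist_pct = 6.09, fut_pct = 8.76)$change_factor, 1.44)
  expect_equal(summary_arithmetic(hist_pct = 9.96, fut_pct = 6.78)$change_factor, 0.68)
  expect_equal(summary_arithmetic(hist_pct = 70.93, fut_pct = 74.35)$change_factor, 1.05)
  expect_error(summary_arithmetic(hist_pct = 0, fut_pct = 1), "undefined")
})
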