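test_that("multiplicative QDM matches the hand-evaluated small instance", {
  out <- qdm_correct(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 8, 12, 16),
                     kind = "multiplicative")
  expect_equal(as.numeric(out), c(2, 4, 6, 8))
})

test_that("QDM is the identity when all three series coincide", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  for (kind in c("multiplicative", "additive")) {
    out <- qdm_correct(x, x, x, kind = kind)
    expect_equal(as.numeric(out), x)
  }
})

test_that("additive QDM maps a uniform shift onto reference quantiles", {
  hist <- c(2, 5, 7, 11)
  ref <- c(1, 2, 3, 4)
  out <- qdm_correct(ref, hist, hist + 3, kind = "additive")
  expect_equal(as.numeric(out), sort(ref)[rank(hist)] + 3)
})

test_that("QDM agrees exactly with a brute-force evaluation of its definition", {
  set.seed(7)
  for (rep in 1:5) {
    nr <- sample(5:40, 1); nh <- sample(5:40, 1); np <- sample(5:40, 1)
    ref <- runif(nr, 1, 10); hist <- runif(nh, 2, 12); proj <- runif(np, 3, 15)
    for (kind in c("multiplicative", "additive")) {
      impl <- as.numeric(qdm_correct(ref, hist, proj, kind = kind))
      orac <- qdm_oracle(ref, hist, proj, kind)
      expect_equal(impl, orac, tolerance = 1e-12)
    }
  }
})

test_that("multiplicative QDM preserves projected/historic quantile ratios", {
  ref <- c(1, 2, 3, 4); hist <- c(2, 4, 6, 8); proj <- c(4, 8, 12, 16)
  corrected <- as.numeric(qdm_correct(ref, hist, proj, kind = "multiplicative"))
  corrected_hist <- as.numeric(qdm_correct(ref, hist, hist, kind = "multiplicative"))
  # at every knot tau: corrected_proj_q / corrected_hist_q == proj_q / hist_q
  expect_equal(sort(corrected) / sort(corrected_hist), sort(proj) / sort(hist))

  set.seed(3)
  ref <- sort(runif(20, 5, 10)); hist <- sort(runif(20, 4, 9))
  proj <- hist * 1.3   # known relative change at every quantile
  corrected <- as.numeric(qdm_correct(ref, hist, proj, kind = "multiplicative"))
  corrected_hist <- as.numeric(qdm_correct(ref, hist, hist, kind = "multiplicative"))
  expect_equal(sort(corrected) / sort(corrected_hist), rep(1.3, 20))
})

test_that("grouped QDM corrects within groups and flags empty ones", {
  times <- hourly_times("2001-01-01 00:00:00", 24 * 28)
  gr <- build_time_groups(times, "weekly")$key
  set.seed(1)
  ref <- runif(length(times), 10, 20)
  hist <- runif(length(times), 15, 25)
  proj <- runif(length(times), 15, 25)
  groups <- list(ref = gr, hist = gr, proj = gr)
  out <- qdm_correct(ref, hist, proj, groups = groups, kind = "additive")
  # every group's correction equals the single-group oracle on that group
  for (k in unique(gr)[1:10]) {
    i <- gr == k
    expect_equal(as.numeric(out)[i], qdm_oracle(ref[i], hist[i], proj[i], "additive"),
                 tolerance = 1e-12)
  }
  groups_bad <- list(ref = gr, hist = gr, proj = rep("99.99", length(times)))
  expect_error(qdm_correct(ref, hist, proj, groups = groups_bad), "99\\.99")
})

test_that("non-finite adjustment factors for shortwave are zeroed and counted", {
  f <- c(1.2, Inf, 0.8, NaN, -Inf)
  out <- sanitize_factors(f, "swdown")
  expect_equal(as.numeric(out), c(1.2, 0, 0.8, 0, 0))
  expect_equal(attr(out, "n_replaced"), 3L)

  ok <- sanitize_factors(c(1, 2, 3), "swdown")
  expect_equal(as.numeric(ok), c(1, 2, 3))
  expect_equal(attr(ok, "n_replaced"), 0L)

  expect_warning(sanitize_factors(c(1, Inf), "tair"), "non-finite")
})

test_that("zero model quantiles drive projected shortwave to zero (0/0 included)", {
  # reference has light where the model is always dark: factor Inf -> 0
  ref <- c(0, 0, 5, 6)
  hist <- c(0, 0, 0, 0)
  proj <- c(0, 0, 0, 0)
  out <- qdm_correct(ref, hist, proj, kind = "multiplicative", variable = "swdown")
  expect_equal(as.numeric(out), rep(0, 4))
  expect_gt(attr(out, "n_replaced"), 0)
})

test_that("full met QDM aligns historical marginals with the reference", {
  cfg <- synth_config(start_year = 2000, end_year = 2001,
                      bias = list(offset = c(tair = 2, rh = -5),
                                  scale = c(wind10 = 1.4, swdown = 0.85)))
  ref <- gen_reference_series(cfg, 21)
  pair <- gen_model_pair(cfg, 22)
  corr <- qdm_correct_met(ref, pair$historical, pair$historical)
  # period means realign despite the injected biases
  expect_lt(abs(mean(corr$tair) - mean(ref$tair)), 0.1)
  expect_lt(abs(mean(corr$wind10) - mean(ref$wind10)), 0.1)
  expect_lt(abs(mean(corr$swdown) - mean(ref$swdown)), 5)
  # deciles of corrected historical match reference deciles
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_lt(max(abs(quantile(corr$tair, qs) - quantile(ref$tair, qs))), 0.25)
})
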