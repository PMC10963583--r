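test_that("same config and seed reproduce a bit-identical series", {
  cfg <- synth_config()
  a <- gen_reference_series(cfg, 42)
  b <- gen_reference_series(cfg, 42)
  expect_identical(met_matrix(a), met_matrix(b))
  c <- gen_reference_series(cfg, 43)
  expect_false(identical(met_matrix(a), met_matrix(c)))
})

test_that("degenerate config (zero amplitudes and noise) gives constant tair", {
  cfg <- synth_config(diurnal_amp = c(tair = 0, rh = 0, wind10 = 0),
                      annual_amp = c(tair = 0, rh = 0, wind10 = 0),
                      noise_sd = c(tair = 0, rh = 0, wind10 = 0, cloud = 0))
  s <- gen_reference_series(cfg, 1)
  expect_true(all(s$tair == cfg$mean[["tair"]]))
})

test_that("10-year run matches configured mean, AR(1) and innovation correlations", {
  cfg <- synth_config(start_year = 2000, end_year = 2009)
  s <- gen_reference_series(cfg, 11)

  # configured mean within 3 standard errors (AR(1)-inflated)
  n <- nrow(s)
  rho <- cfg$ar1[["tair"]]
  sd_stat <- cfg$noise_sd[["tair"]] / sqrt(1 - rho^2)
  se <- sd_stat * sqrt((1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(s$tair) - cfg$mean[["tair"]]), 3 * se)

  # lag-1 autocorrelation of each latent channel within +/- 0.05
  lat <- attr(s, "latents")
  for (j in 1:4) {
    ac <- acf(lat[, j], lag.max = 1, plot = FALSE)$acf[2]
    expect_lt(abs(ac - cfg$ar1[j]), 0.05)
  }

  # innovation cross-correlations within +/- 0.05 of the configured matrix
  emp <- cor(attr(s, "innovations"))
  expect_lt(max(abs(emp - cfg$cross_cor)), 0.05)
})

test_that("physical bounds hold on every generated series", {
  for (seed in 1:3) {
    s <- gen_reference_series(synth_config(), seed)
    expect_true(all(s$rh >= 0 & s$rh <= 100))
    expect_true(all(s$wind10 >= 0))
    expect_true(all(s$swdown >= 0))
    sun <- solar_position(s$time, attr(s, "latitude"), attr(s, "longitude"))
    expect_true(all(s$swdown[sun$elevation <= 0] == 0))
  }
})

test_that("invalid configurations are rejected", {
  bad_cor <- diag(4); bad_cor[1, 2] <- bad_cor[2, 1] <- 1.2
  expect_error(synth_config(cross_cor = bad_cor), "positive definite")
  expect_error(synth_config(ar1 = c(tair = 1, rh = .5, wind10 = .5, cloud = .5)),
               "ar1")
  expect_error(synth_config(diurnal_amp = c(tair = -1, rh = 0, wind10 = 0)),
               "amplitudes")
})

test_that("model pair carries the configured change signal and bias", {
  cfg <- synth_config(start_year = 2000, end_year = 2009,
                      change = list(tair = 2, rh = 1, wind10 = 1, swdown = 1),
                      bias = list(offset = c(tair = 0, rh = 0),
                                  scale = c(wind10 = 1.5, swdown = 1)))
  pair <- gen_model_pair(cfg, 5)
  n <- nrow(pair$historical)
  rho <- cfg$ar1[["tair"]]
  sd_stat <- cfg$noise_sd[["tair"]] / sqrt(1 - rho^2)
  se_diff <- sqrt(2) * sd_stat * sqrt((1 + rho) / (1 - rho) / n)
  expect_lt(abs(mean(pair$future$tair) - mean(pair$historical$tair) - 2),
            3 * se_diff)

  ref <- gen_reference_series(cfg, 6)
  expect_lt(abs(mean(pair$historical$wind10) / mean(ref$wind10) - 1.5), 0.1)
})

test_that("zero-bias model is statistically indistinguishable from the reference", {
  cfg <- synth_config(start_year = 2000, end_year = 2002)
  ps <- vapply(1:5, function(i) {
    ref <- gen_reference_series(cfg, 100 + i)
    pair <- gen_model_pair(cfg, 200 + i)
    # decorrelate by daily subsampling before the two-sample KS test
    idx <- seq(13, nrow(ref), by = 24)
    suppressWarnings(ks.test(ref$tair[idx], pair$historical$tair[idx])$p.value)
  }, numeric(1))
  expect_gt(median(ps), 0.05)
})
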