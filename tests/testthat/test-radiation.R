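night_sun <- data.frame(azimuth = 0, zenith = 120, elevation = -30)

test_that("isothermal enclosure: every longwave component is sigma*T^4 and T_mrt = T_air", {
  svf0 <- matrix(0, 3, 3)
  for (ta in c(-5, 10, 25)) {
    lw <- longwave_components(ta, 60, 0, svf0, night_sun)
    bb <- 5.670374419e-8 * (ta + 273.15)^4
    expect_equal(max(abs(lw$ldown - bb)), 0, tolerance = 1e-9)
    expect_equal(max(abs(lw$lup - bb)), 0, tolerance = 1e-9)
    expect_equal(max(abs(lw$llat - bb)), 0, tolerance = 1e-9)
    zero <- matrix(0, 3, 3)
    sstr <- mean_radiant_flux(list(kdown = zero, kup = zero, klat = zero,
                                   ldown = lw$ldown, lup = lw$lup, llat = lw$llat))
    expect_equal(max(abs(tmrt_from_sstr(sstr) - ta)), 0, tolerance = 1e-9)
  }
})

test_that("downwelling longwave increases with humidity under a clear sky", {
  svf1 <- matrix(1, 2, 2)
  lds <- vapply(c(20, 40, 60, 80), function(rh) {
    longwave_components(15, rh, 0, svf1, night_sun, cloud_fraction = 0)$ldown[1, 1]
  }, numeric(1))
  expect_true(all(diff(lds) > 0))
})

test_that("an overcast night sky radiates like a blackbody at air temperature", {
  svf1 <- matrix(1, 2, 2)
  lw <- longwave_components(10, 80, 0, svf1, night_sun, cloud_fraction = 1)
  expect_equal(lw$ldown[1, 1], 5.670374419e-8 * 283.15^4, tolerance = 1e-6)
})

test_that("mean radiant flux honours view weights, linearity and positivity", {
  bb0 <- 5.670374419e-8 * 273.15^4
  iso <- list(kdown = 0, kup = 0, klat = 0, ldown = bb0, lup = bb0, llat = bb0)
  expect_equal(mean_radiant_flux(iso), 0.97 * bb0)
  b <- list(kdown = 300, kup = 60, klat = 150, ldown = 350, lup = 400, llat = 380)
  expect_equal(mean_radiant_flux(lapply(b, `*`, 2)), 2 * mean_radiant_flux(b))
  expect_error(mean_radiant_flux(modifyList(b, list(kup = -1))), ">= 0")
})

test_that("S_str is bounded by absorbed total shortwave plus emitted max longwave", {
  b <- list(kdown = 500, kup = 100, klat = 200, ldown = 340, lup = 420, llat = 390)
  s <- mean_radiant_flux(b)
  bound <- 0.7 * (b$kdown + b$kup + 4 * b$klat) + 0.97 * max(b$ldown, b$lup, b$llat)
  expect_lt(s, bound)
})

test_that("the radiant temperature inversion is exact and strictly increasing", {
  sig <- 5.670374419e-8
  expect_equal(tmrt_from_sstr(0.97 * sig * 273.15^4), 0, tolerance = 1e-9)
  expect_equal(tmrt_from_sstr(0.97 * sig * 300^4), 26.85, tolerance = 1e-9)
  s <- seq(100, 700, by = 50)
  expect_true(all(diff(tmrt_from_sstr(s)) > 0))
  expect_error(tmrt_from_sstr(-1), ">= 0")
})

test_that("shaded cells are radiatively cooler than sunlit neighbours in strong sun", {
  r <- mixed_scene()
  svf <- sky_view_factor(r, n_dirs = 36, max_dist = 30)
  met <- list(time = as.POSIXct("2001-01-15 13:00:00", tz = "Etc/GMT-10"),
              tair = 28, rh = 40, wind10 = 2, swdown = 900)
  g <- compute_tmrt_grid(r, svf, met, -42.883, 147.330)
  shaded <- g$shadow$factor < 1
  expect_gt(mean(g$tmrt[!shaded]) - mean(g$tmrt[shaded]), 5)
  expect_gt(diff(range(g$tmrt)), 10)
})

test_that("night grids come from longwave only, with no shadow computation", {
  r <- mixed_scene()
  svf <- sky_view_factor(r, n_dirs = 36, max_dist = 30)
  met <- list(time = as.POSIXct("2001-01-15 02:00:00", tz = "Etc/GMT-10"),
              tair = 15, rh = 60, wind10 = 2, swdown = 0)
  g <- compute_tmrt_grid(r, svf, met, -42.883, 147.330)
  expect_null(g$shadow)
  expect_true(all(g$budget$kdown == 0))
  expect_true(all(is.finite(g$tmrt)))
})

test_that("tiled evaluation equals the untiled grid given an adequate buffer", {
  r <- mixed_scene()
  tms <- hourly_times("2001-01-15 11:00:00", 3)
  met <- met_series(tms, c(24, 25, 26), c(50, 48, 45), c(3, 3, 3),
                    c(700, 850, 800))
  p <- radiation_params(svf_max_dist = 20)
  whole <- run_tiled(r, met, tile = 60, buffer = 20, params = p)
  tiled <- run_tiled(r, met, tile = 30, buffer = 20, params = p)
  expect_lt(max(abs(whole - tiled)), 1e-9)
})

test_that("tiling layout is as specified: a 150 m site with 50 m tiles gives 9 tiles", {
  wins <- heatscape:::tile_windows(150, 150, 50, 50)
  expect_length(wins, 9)
  expect_error(run_tiled(mixed_scene(), flat_met(hourly_times("2001-01-01 00:00:00", 1)),
                         tile = 30, buffer = 0.5),
               "buffer")
})
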