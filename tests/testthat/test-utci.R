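test_that("vapour pressure: zero humidity, monotonicity, closed-form value", {
  expect_equal(vapour_pressure(20, 0), 0)
  expect_equal(vapour_pressure(20, 50), 11.7, tolerance = 0.01)
  t <- seq(-10, 40, by = 5)
  expect_true(all(diff(vapour_pressure(t, 50)) > 0))
  expect_true(all(diff(vapour_pressure(20, seq(10, 90, 10))) > 0))
})

test_that("UTCI agrees with the independent table-driven evaluation within 0.01 degC", {
  set.seed(5)
  n <- 1500
  ta <- runif(n, -40, 45)
  va <- runif(n, 0.5, 17)
  dt <- runif(n, -25, 60)
  rh <- runif(n, 5, 95)
  pa <- vapour_pressure(ta, rh) / 10
  impl <- as.numeric(utci(ta, ta + dt, va, rh))
  orac <- utci_oracle(ta, va, dt, pa)
  expect_lt(max(abs(impl - orac)), 0.01)
})

test_that("UTCI tracks air temperature at the reference state", {
  ta <- seq(-10, 35, by = 0.5)
  u <- as.numeric(utci(ta, ta, 0.5, utci_reference_rh(ta)))
  expect_lt(max(abs(u - ta)), 1.2)
})

test_that("UTCI rises with radiant load and falls with wind", {
  u0 <- as.numeric(utci(20, 20, 2, 50))
  u1 <- as.numeric(utci(20, 40, 2, 50))
  expect_gt(u1, u0)
  expect_lt(as.numeric(utci(0, 0, 10, 50)), as.numeric(utci(0, 0, 0.5, 50)))
})

test_that("inputs outside the validity window are clamped and flagged", {
  u <- utci(c(20, 20), c(20, 20), c(0.1, 2), c(50, 50))
  expect_true(attr(u, "clamped")[1])
  expect_false(attr(u, "clamped")[2])
  expect_equal(as.numeric(u)[1], as.numeric(utci(20, 20, 0.5, 50)))
  expect_error(utci(NA, 20, 2, 50), "non-finite")
})

test_that("UTCI stays finite and within plausible bounds on a dense valid grid", {
  grid <- expand.grid(ta = seq(-45, 45, by = 5), dt = seq(-25, 65, by = 5),
                      va = c(0.5, 2, 8, 16), rh = c(10, 50, 90))
  # the polynomial is calibrated for vapour pressures up to 50 hPa
  grid <- grid[vapour_pressure(grid$ta, grid$rh) <= 50, ]
  u <- as.numeric(utci(grid$ta, grid$ta + grid$dt, grid$va, grid$rh))
  expect_true(all(is.finite(u)))
  expect_true(all(u > -90 & u < 70))
})

test_that("stress categories use strict thresholds with boundaries in the milder class", {
  cls <- classify_stress(c(26.0, 26.1, 0.0, -0.1, 39, 47, -41, 33))
  expect_equal(as.character(cls$category),
               c("no stress", "moderate heat", "no stress", "moderate cold",
                 "very strong heat", "extreme heat", "extreme cold", "strong heat"))
  expect_equal(cls$any_heat, c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(cls$any_cold, c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("rollups are consistent with the ordered category scale", {
  u <- seq(-50, 60, by = 0.7)
  cls <- classify_stress(u)
  expect_equal(cls$any_heat, cls$category >= "moderate heat")
  expect_equal(cls$any_cold, cls$category <= "moderate cold")
  expect_error(classify_stress(c(1, NA)), "finite")
})
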