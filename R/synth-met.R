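#' Configuration for the synthetic meteorology generator
#'
#' Defines a four-variable hourly process with diurnal and annual harmonic
#' cycles, cross-correlated AR(1) innovations, a stochastic cloud channel for
#' shortwave, configurable model biases and a configurable future change
#' signal. Air temperature is generated on its natural scale; relative
#' humidity on the logit scale of `rh/100` and wind on the log scale (their
#' configured means are medians after back-transformation, and their
#' amplitudes/noise are in logit and log units respectively). Shortwave is a
#' clear-sky envelope times a beta-distributed cloud transmittance whose
#' Gaussian copula mixes a day-to-day AR(1) latent with the fourth
#' cross-correlated hourly innovation channel.
#'
#' @param mean named means: `tair` (degC), `rh` (%, median), `wind10`
#'   (m/s, median). Shortwave has no configured mean (clear-sky x cloud).
#' @param diurnal_amp,annual_amp cycle amplitudes per latent channel
#'   (`tair`, `rh`, `wind10`); degC / logit / log units.
#' @param diurnal_phase hour of daily peak per channel (local standard time).
#' @param annual_phase day of year of annual peak per channel.
#' @param ar1 AR(1) coefficients in `[0, 1)` for the four latent channels
#'   (`tair`, `rh`, `wind10`, `cloud`).
#' @param noise_sd innovation standard deviations for the four channels.
#' @param cross_cor 4x4 innovation correlation matrix (symmetric positive
#'   definite, unit diagonal), channel order `tair`, `rh`, `wind10`, `cloud`.
#' @param bias per-variable model bias: list with `offset` (tair degC; rh
#'   percentage points) and `scale` (multiplicative, wind10/swdown).
#' @param change future change signal: `tair` additive degC, a scalar or a
#'   length-4 vector per austral season `c(DJF, MAM, JJA, SON)`; `rh`,
#'   `wind10`, `swdown` multiplicative scalars.
#' @param cloud_shape1,cloud_shape2 beta parameters of the hourly cloud
#'   transmittance.
#' @param cloud_day_ar1 day-to-day AR(1) of the daily cloud latent.
#' @param cloud_day_weight weight of the daily latent in the copula mix
#'   (`0` = purely hourly, `1` = purely daily).
#' @param latitude,longitude site coordinates (deg; default central Hobart).
#' @param utc_offset fixed local-standard-time offset from UTC in hours.
#' @param start_year,end_year inclusive calendar years of the series.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(mean = c(tair = 12.1, rh = 70, wind10 = 3.0),
                         diurnal_amp = c(tair = 4, rh = 0.5, wind10 = 0.25),
                         annual_amp = c(tair = 5, rh = 0.3, wind10 = 0.15),
                         diurnal_phase = c(tair = 15, rh = 4, wind10 = 15),
                         annual_phase = c(tair = 25, rh = 205, wind10 = 25),
                         ar1 = c(tair = 0.9, rh = 0.9, wind10 = 0.8, cloud = 0.95),
                         noise_sd = c(tair = 0.8, rh = 0.15, wind10 = 0.2, cloud = 0.3),
                         cross_cor = default_cross_cor(),
                         bias = list(offset = c(tair = 0, rh = 0),
                                     scale = c(wind10 = 1, swdown = 1)),
                         change = list(tair = 0, rh = 1, wind10 = 1, swdown = 1),
                         cloud_shape1 = 1.2, cloud_shape2 = 0.6,
                         cloud_day_ar1 = 0.6, cloud_day_weight = 0.7,
                         latitude = -42.883, longitude = 147.330,
                         utc_offset = 10,
                         start_year = 2000, end_year = 2000) {
  cfg <- list(mean = mean, diurnal_amp = diurnal_amp, annual_amp = annual_amp,
              diurnal_phase = diurnal_phase, annual_phase = annual_phase,
              ar1 = ar1, noise_sd = noise_sd, cross_cor = cross_cor,
              bias = bias, change = change,
              cloud_shape1 = cloud_shape1, cloud_shape2 = cloud_shape2,
              cloud_day_ar1 = cloud_day_ar1, cloud_day_weight = cloud_day_weight,
              latitude = latitude, longitude = longitude,
              utc_offset = utc_offset,
              start_year = start_year, end_year = end_year)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Default innovation cross-correlation matrix
#'
#' Warm hours tend to be drier and clearer; wind is weakly coupled.
#' @return 4x4 correlation matrix (tair, rh, wind10, cloud).
#' @export
default_cross_cor <- function() {
  r <- matrix(c(
     1.0, -0.5,  0.1,  0.3,
    -0.5,  1.0, -0.1, -0.4,
     0.1, -0.1,  1.0,  0.0,
     0.3, -0.4,  0.0,  1.0), 4, 4)
  dimnames(r) <- list(c(MET_VARS[1:3], "cloud"), c(MET_VARS[1:3], "cloud"))
  r
}

validate_synth_config <- function(cfg) {
  r <- cfg$cross_cor
  if (!isTRUE(all.equal(r, t(r))) || any(abs(diag(r) - 1) > 1e-12)) {
    stop("cross_cor must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("cross_cor must be positive definite", call. = FALSE)
  if (any(cfg$diurnal_amp < 0) || any(cfg$annual_amp < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (any(cfg$ar1 < 0 | cfg$ar1 >= 1)) stop("ar1 must lie in [0, 1)", call. = FALSE)
  if (any(cfg$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$end_year < cfg$start_year) stop("end_year < start_year", call. = FALSE)
  invisible(cfg)
}

synth_tz <- function(cfg) sprintf("Etc/GMT%+d", -cfg$utc_offset)

synth_times <- function(cfg, start_year = cfg$start_year, end_year = cfg$end_year) {
  tz <- synth_tz(cfg)
  seq(as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = tz),
      as.POSIXct(sprintf("%d-12-31 23:00:00", end_year), tz = tz),
      by = 3600)
}

# Deterministic harmonic cycle for latent channel v at the given local times.
harmonic_cycle <- function(cfg, v, time) {
  lt <- as.POSIXlt(time)
  hour <- lt$hour
  doy <- lt$yday + 1
  base <- if (v == "tair") cfg$mean[["tair"]]
    else if (v == "rh") stats::qlogis(cfg$mean[["rh"]] / 100)
    else log(cfg$mean[["wind10"]])
  base +
    cfg$diurnal_amp[[v]] * cos(2 * pi * (hour - cfg$diurnal_phase[[v]]) / 24) +
    cfg$annual_amp[[v]] * cos(2 * pi * (doy - cfg$annual_phase[[v]]) / 365.25)
}

# Correlated AR(1) latents for the four channels; returns list(latents,
# innovations) as n x 4 matrices (standard-normal innovations pre-scaling).
synth_latents <- function(cfg, n) {
  ch <- chol(cfg$cross_cor)
  z <- matrix(rnorm(n * 4), n, 4) %*% ch     # unit-variance correlated innovations
  lat <- matrix(0, n, 4)
  for (j in 1:4) {
    lat[, j] <- as.numeric(stats::filter(z[, j] * cfg$noise_sd[j],
                                         cfg$ar1[j], method = "recursive"))
  }
  list(latents = lat, innovations = z)
}

# Hourly cloud transmittance in (0,1): Gaussian copula over a mix of a daily
# AR(1) latent and the hourly cloud channel latent (standardised).
cloud_transmittance <- function(cfg, time, cloud_latent) {
  n <- length(time)
  day_idx <- as.integer(floor(as.numeric(time) / 86400))
  day_idx <- day_idx - day_idx[1] + 1
  nd <- max(day_idx)
  zd <- as.numeric(stats::filter(rnorm(nd, sd = sqrt(1 - cfg$cloud_day_ar1^2)),
                                 cfg$cloud_day_ar1, method = "recursive"))
  sd_h <- cfg$noise_sd[["cloud"]] / sqrt(1 - cfg$ar1[["cloud"]]^2)
  zh <- cloud_latent / max(sd_h, 1e-12)
  w <- cfg$cloud_day_weight
  u <- pnorm(w * zd[day_idx] + sqrt(1 - w^2) * zh)
  qbeta(u, cfg$cloud_shape1, cfg$cloud_shape2)
}

# Back-transform latents to the natural scales and assemble a met_series.
assemble_series <- function(cfg, time, lat_mat, innovations) {
  cyc <- sapply(c("tair", "rh", "wind10"), function(v) harmonic_cycle(cfg, v, time))
  tair <- cyc[, "tair"] + lat_mat[, 1]
  rh <- 100 * stats::plogis(cyc[, "rh"] + lat_mat[, 2])
  wind <- exp(cyc[, "wind10"] + lat_mat[, 3])
  sun <- solar_position(time, cfg$latitude, cfg$longitude)
  csky <- clear_sky_shortwave(sun)
  sw <- csky * cloud_transmittance(cfg, time, lat_mat[, 4])
  out <- met_series(time, tair, rh, wind, sw,
                    latitude = cfg$latitude, longitude = cfg$longitude)
  attr(out, "latents") <- lat_mat
  attr(out, "innovations") <- innovations
  out
}

#' Generate a synthetic reference ("reanalysis") series
#'
#' @param config a [synth_config()].
#' @param seed integer seed; identical config and seed give a bit-identical
#'   series.
#' @return a [met_series()] with attributes `latents` and `innovations`
#'   (n x 4 matrices of the latent anomalies and their unit-variance
#'   correlated innovations) for calibration checks.
#' @export
gen_reference_series <- function(config, seed) {
  validate_synth_config(config)
  time <- synth_times(config)
  withr_seed(seed, {
    l <- synth_latents(config, length(time))
    assemble_series(config, time, l$latents, l$innovations)
  })
}

#' Generate a biased model pair (historical, future)
#'
#' The historical member shares the reference generator structure with the
#' configured biases applied; the future member additionally carries the
#' configured change signal, so the "true" change is known by construction.
#'
#' @param config a [synth_config()]; its `start_year`/`end_year` give the
#'   historical period.
#' @param seed integer seed.
#' @param future_years length-2 integer vector `c(start, end)` of the future
#'   period (defaults to the historical span shifted 50 years).
#' @return list with elements `historical` and `future`, both [met_series()].
#' @export
gen_model_pair <- function(config, seed, future_years = NULL) {
  validate_synth_config(config)
  if (is.null(future_years)) {
    future_years <- c(config$start_year, config$end_year) + 50
  }
  hist_time <- synth_times(config)
  fut_time <- synth_times(config, future_years[1], future_years[2])
  withr_seed(seed, {
    lh <- synth_latents(config, length(hist_time))
    hist <- assemble_series(config, hist_time, lh$latents, lh$innovations)
    hist <- apply_bias(config, hist)
    lf <- synth_latents(config, length(fut_time))
    fut <- assemble_series(config, fut_time, lf$latents, lf$innovations)
    fut <- apply_bias(config, fut)
    fut <- apply_change(config, fut)
  })
  list(historical = hist, future = fut)
}

apply_bias <- function(cfg, x) {
  m <- met_matrix(x)
  b <- cfg$bias
  m[, "tair"] <- m[, "tair"] + b$offset[["tair"]]
  m[, "rh"] <- pmin(100, pmax(0, m[, "rh"] + b$offset[["rh"]]))
  m[, "wind10"] <- m[, "wind10"] * b$scale[["wind10"]]
  m[, "swdown"] <- m[, "swdown"] * b$scale[["swdown"]]
  out <- met_replace(x, m)
  attr(out, "latents") <- attr(x, "latents")
  attr(out, "innovations") <- attr(x, "innovations")
  out
}

# Austral season index per timestamp: 1 DJF, 2 MAM, 3 JJA, 4 SON.
season_index <- function(time) {
  mon <- as.POSIXlt(time)$mon + 1
  c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)[mon]
}

apply_change <- function(cfg, x) {
  m <- met_matrix(x)
  dtair <- cfg$change$tair
  if (length(dtair) == 1) dtair <- rep(dtair, 4)
  m[, "tair"] <- m[, "tair"] + dtair[season_index(x$time)]
  m[, "rh"] <- pmin(100, pmax(0, m[, "rh"] * cfg$change$rh))
  m[, "wind10"] <- m[, "wind10"] * cfg$change$wind10
  m[, "swdown"] <- m[, "swdown"] * cfg$change$swdown
  out <- met_replace(x, m)
  attr(out, "latents") <- attr(x, "latents")
  attr(out, "innovations") <- attr(x, "innovations")
  out
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
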