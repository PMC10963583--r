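#' Solar position (NOAA closed-form algorithm)
#'
#' Astronomical solar azimuth and zenith from the NOAA solar-calculator
#' equations (geometric mean longitude/anomaly, equation of centre, apparent
#' longitude, corrected obliquity, equation of time). No atmospheric
#' refraction is applied.
#'
#' @param time POSIXct vector (any time zone; converted to UTC internally).
#' @param latitude,longitude degrees; south and west negative.
#' @return data frame with columns `azimuth` (deg clockwise from north,
#'   `[0, 360)`), `zenith` (deg) and `elevation` (deg, `90 - zenith`).
#' @export
solar_position <- function(time, latitude, longitude) {
  d2r <- pi / 180
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  l0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  m  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(m * d2r) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * m * d2r) * (0.019993 - 0.000101 * jc) +
    sin(3 * m * d2r) * 0.000289
  true_long <- l0 + ctr
  omega <- 125.04 - 1934.136 * jc
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * d2r)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cos(omega * d2r)
  decl <- asin(sin(obliq * d2r) * sin(app_long * d2r))

  y <- tan(obliq / 2 * d2r)^2
  eqtime <- 4 / d2r * (y * sin(2 * l0 * d2r) - 2 * ecc * sin(m * d2r) +
    4 * ecc * y * sin(m * d2r) * cos(2 * l0 * d2r) -
    0.5 * y^2 * sin(4 * l0 * d2r) - 1.25 * ecc^2 * sin(2 * m * d2r))

  utc_minutes <- (as.numeric(time) %% 86400) / 60
  tst <- (utc_minutes + eqtime + 4 * longitude) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360

  lat_r <- latitude * d2r
  cos_zen <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha * d2r)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zenith <- acos(cos_zen) / d2r

  az_denom <- cos(lat_r) * sin(zenith * d2r)
  azimuth <- numeric(length(jd))
  ok <- abs(az_denom) > 1e-6
  az_rad <- pmin(1, pmax(-1, (sin(lat_r) * cos_zen[ok] - sin(decl[ok])) / az_denom[ok]))
  az <- 180 - acos(az_rad) / d2r
  az[ha[ok] > 0] <- -az[ha[ok] > 0]
  azimuth[ok] <- az %% 360
  azimuth[!ok] <- ifelse(latitude > 0, 180, 0)

  data.frame(azimuth = azimuth, zenith = zenith, elevation = 90 - zenith)
}

#' Clear-sky global horizontal irradiance
#'
#' Simple broadband transmittance model: direct-beam transmittance
#' `0.7^(AM^0.678)` of the solar constant (Meinel form) projected on the
#' horizontal, with air mass from the Kasten-Young relation. Zero when the sun
#' is at or below the horizon. Intended for cloud-fraction estimation and
#' synthetic forcing, not for radiometric accuracy.
#'
#' @param sun data frame from [solar_position()].
#' @return numeric vector of clear-sky GHI (W/m2).
#' @export
clear_sky_shortwave <- function(sun) {
  elev <- sun$elevation
  out <- numeric(length(elev))
  up <- elev > 0
  z <- sun$zenith[up]
  am <- 1 / (cos(z * pi / 180) + 0.50572 * (96.07995 - z)^(-1.6364))
  out[up] <- SOLAR_CONSTANT * 0.7^(am^0.678) * cos(z * pi / 180)
  out
}

#' Split global shortwave into direct-normal and diffuse-horizontal
#'
#' Diffuse fraction from the Erbs clearness-index relation; clearness index is
#' the ratio of measured global to extraterrestrial horizontal irradiance.
#' Direct-normal irradiance is capped at the solar constant (diffuse absorbs
#' the remainder) so the closure `dni * cos(zenith) + dhi = swdown` always
#' holds.
#'
#' @param swdown global horizontal irradiance (W/m2), `>= 0`.
#' @param sun data frame from [solar_position()] (recycled if length 1).
#' @return data frame with columns `dni` (direct normal, W/m2) and `dhi`
#'   (diffuse horizontal, W/m2).
#' @export
split_direct_diffuse <- function(swdown, sun) {
  stopifnot(all(swdown >= 0))
  n <- max(length(swdown), nrow(sun))
  swdown <- rep_len(swdown, n)
  elev <- rep_len(sun$elevation, n)
  zen <- rep_len(sun$zenith, n)
  dni <- dhi <- numeric(n)

  night <- elev <= 0
  if (any(night & swdown > 0)) {
    warning("positive swdown with sun below horizon: treated as all diffuse")
    dhi[night] <- swdown[night]
  }

  up <- !night & swdown > 0
  if (any(up)) {
    cosz <- cos(zen[up] * pi / 180)
    kt <- pmax(0, swdown[up] / (SOLAR_CONSTANT * cosz))
    df <- erbs_diffuse_fraction(kt)
    dhi_u <- df * swdown[up]
    dni_u <- (swdown[up] - dhi_u) / cosz
    over <- dni_u > SOLAR_CONSTANT
    dni_u[over] <- SOLAR_CONSTANT
    dhi_u[over] <- swdown[up][over] - dni_u[over] * cosz[over]
    dni[up] <- dni_u
    dhi[up] <- pmax(0, dhi_u)
  }
  data.frame(dni = dni, dhi = dhi)
}

#' Erbs diffuse fraction from clearness index
#'
#' @param kt clearness index (global / extraterrestrial horizontal), `>= 0`.
#' @return diffuse fraction in `[0, 1]`.
#' @export
erbs_diffuse_fraction <- function(kt) {
  df <- ifelse(kt <= 0.22, 1 - 0.09 * kt,
    ifelse(kt <= 0.80,
      0.9511 - 0.1604 * kt + 4.388 * kt^2 - 16.638 * kt^3 + 12.336 * kt^4,
      0.165))
  pmin(1, pmax(0, df))
}
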