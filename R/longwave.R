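#' Longwave flux components at every cell
#'
#' Clear-sky atmospheric emissivity follows Prata's closed form in
#' precipitable water derived from vapour pressure; cloudiness raises the
#' effective sky emissivity via the Crawford-Duchon mixing
#' `eps = clf + (1 - clf) * eps_clear`, with the cloud fraction taken from
#' the ratio of observed to clear-sky shortwave when the sun is up.
#' Surface temperature is parameterised as air temperature plus a warming
#' proportional to the shortwave reaching the cell. Reflected longwave is
#' closed with a blackbody-at-air-temperature ambient term, which makes an
#' isothermal enclosure radiate exactly `sigma * T_air^4` in every direction.
#'
#' @param tair air temperature (degC, scalar).
#' @param rh relative humidity (%, scalar).
#' @param swdown global shortwave (W/m2, scalar).
#' @param svf sky-view-factor matrix.
#' @param sun single-row data frame from [solar_position()].
#' @param params a [radiation_params()].
#' @param shadow_factor shortwave transmission matrix from [cast_shadow()]
#'   (1 = sunlit); scalar 1 at night.
#' @param cloud_fraction optional override in `[0, 1]`; when `NULL` it is
#'   derived from `swdown` by day and taken as 0 (clear) by night.
#' @return list of matrices `ldown`, `lup`, `llat` (W/m2), plus the scalar
#'   `cloud_fraction` used.
#' @export
longwave_components <- function(tair, rh, swdown, svf, sun, params = radiation_params(),
                                shadow_factor = 1, cloud_fraction = NULL) {
  ta_k <- tair + 273.15
  e_hpa <- vapour_pressure(tair, rh)
  w <- 46.5 * e_hpa / ta_k
  eps_clear <- 1 - (1 + w) * exp(-sqrt(1.2 + 3 * w))
  if (is.null(cloud_fraction)) {
    if (sun$elevation > 0) {
      csky <- clear_sky_shortwave(sun)
      cloud_fraction <- if (csky > 0) 1 - min(1, max(0, swdown / csky)) else 0
    } else {
      cloud_fraction <- 0
    }
  }
  eps_sky <- cloud_fraction + (1 - cloud_fraction) * eps_clear
  l_sky <- eps_sky * SIGMA_SB * ta_k^4

  k_cell <- swdown * shadow_factor
  t_surf_k <- ta_k + params$surface_warming * k_cell / CSKY_MAX
  eps_s <- params$surface_emissivity
  l_amb <- SIGMA_SB * ta_k^4
  l_surface <- eps_s * SIGMA_SB * t_surf_k^4 + (1 - eps_s) * l_amb

  ldown <- svf * l_sky + (1 - svf) * l_surface
  lup <- eps_s * SIGMA_SB * t_surf_k^4 + (1 - eps_s) * ldown
  llat <- 0.5 * (ldown + lup)
  dims <- dim(as.matrix(svf))
  as_grid <- function(x) if (is.matrix(x)) x else matrix(x, dims[1], dims[2])
  list(ldown = as_grid(ldown), lup = as_grid(lup), llat = as_grid(llat),
       cloud_fraction = cloud_fraction)
}
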