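# Shift a matrix by integer (dr, dc): out[r, c] = m[r + dr, c + dc], `fill`
# outside the grid. Row 1 is the northern edge.
shift_matrix <- function(m, dr, dc, fill = -Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  if (abs(dr) >= nr || abs(dc) >= nc) return(out)
  r_src <- (1 + max(0, dr)):(nr + min(0, dr))
  c_src <- (1 + max(0, dc)):(nc + min(0, dc))
  out[r_src - dr, c_src - dc] <- m[r_src, c_src]
  out
}

# Sampled cell offset at horizontal step k toward the sun, and the height
# interval of the ray segment within that step. Shared with the test oracle:
# this IS the discrete geometry being asserted.
shadow_ray_geometry <- function(k, azimuth, elevation, cell_size, eval_height) {
  az <- azimuth * pi / 180
  tan_e <- tan(elevation * pi / 180)
  list(dr = -round(k * cos(az)), dc = round(k * sin(az)),
       h_lo = eval_height + k * cell_size * tan_e,
       h_hi = eval_height + (k + 1) * cell_size * tan_e)
}

#' Cast building and vegetation shadows on a raster scene
#'
#' Marches a ray from each cell toward the sun across the DSM and canopy. A
#' cell is building-shadowed if the ray segment in some sampled cell lies
#' below the built surface, and vegetation-shadowed if the segment overlaps a
#' crown volume (from `trunk_ratio * chm` up to `chm` above ground). The
#' shortwave transmission factor is 0 under buildings, the foliage
#' transmissivity under vegetation only, and 1 when sunlit.
#'
#' @param rasters a [site_rasters()].
#' @param sun single-row data frame from [solar_position()]; the sun must be
#'   above the horizon.
#' @param veg a [veg_params()].
#' @param eval_height height above local ground at which shadows are
#'   evaluated (m; 0 = ground shadows).
#' @param trunk_ratio trunk-zone fraction of canopy height.
#' @param max_dist maximum horizontal search distance (m); defaults to the
#'   distance at which the tallest feature can no longer intercept the ray.
#' @return list with `factor` (transmission in `[0, 1]`), and logical masks
#'   `building`, `vegetation`, `sunlit`.
#' @export
cast_shadow <- function(rasters, sun, veg = veg_params(), eval_height = 0,
                        trunk_ratio = 0.25, max_dist = NULL) {
  if (sun$elevation <= 0) stop("sun below horizon: shadows undefined", call. = FALSE)
  cell <- rasters$cell_size
  dem <- rasters$dem; dsm <- rasters$dsm; chm <- rasters$chm
  tan_e <- tan(sun$elevation * pi / 180)
  top <- max(max(dsm), max(dem + chm))
  k_phys <- ceiling((top - min(dem) - eval_height) / (cell * tan_e))
  k_cap <- ceiling(sqrt(nrow(dem)^2 + ncol(dem)^2))
  if (!is.null(max_dist)) k_cap <- min(k_cap, ceiling(max_dist / cell))
  k_max <- max(0, min(k_phys, k_cap))

  z_eval <- dem + eval_height
  bmask <- matrix(FALSE, nrow(dem), ncol(dem))
  vmask <- bmask
  eps <- 1e-9
  for (k in 0:k_max) {
    g <- shadow_ray_geometry(k, sun$azimuth, sun$elevation, cell, eval_height)
    dem_s <- shift_matrix(dem, g$dr, g$dc, fill = -Inf)
    dsm_s <- shift_matrix(dsm, g$dr, g$dc, fill = -Inf)
    chm_s <- shift_matrix(chm, g$dr, g$dc, fill = 0)
    h_lo <- dem + g$h_lo
    h_hi <- dem + g$h_hi
    bmask <- bmask | (dsm_s > h_lo + eps & dsm_s > dem_s + eps)
    vmask <- vmask | (chm_s > 0 &
                        dem_s + chm_s >= h_lo - eps &
                        dem_s + trunk_ratio * chm_s <= h_hi + eps)
  }
  factor <- matrix(1, nrow(dem), ncol(dem))
  factor[vmask] <- veg$sw_transmissivity
  factor[bmask] <- 0
  list(factor = factor, building = bmask, vegetation = vmask & !bmask,
       sunlit = !bmask & !vmask)
}

#' Sky view factor of every cell
#'
#' Hemispheric integration over azimuthal search directions of the maximum
#' horizon angle: each direction contributes `cos^2` of its horizon angle
#' (the view factor of the unobstructed part of the wedge seen by a
#' horizontal surface). Built surfaces are opaque; vegetation is opaque with
#' weight `1 - lw_transmissivity`.
#'
#' @param rasters a [site_rasters()].
#' @param n_dirs number of azimuthal directions (>= 36 recommended).
#' @param max_dist horizon search distance (m); `NULL` scans the whole grid.
#' @param veg a [veg_params()].
#' @param eval_height evaluation height above local ground (m).
#' @return matrix of SVF values in `[0, 1]`.
#' @export
sky_view_factor <- function(rasters, n_dirs = 48, max_dist = NULL,
                            veg = veg_params(), eval_height = 0) {
  cell <- rasters$cell_size
  dem <- rasters$dem; dsm <- rasters$dsm; chm <- rasters$chm
  nr <- nrow(dem); nc <- ncol(dem)
  k_cap <- ceiling(sqrt(nr^2 + nc^2))
  if (!is.null(max_dist)) k_cap <- min(k_cap, ceiling(max_dist / cell))
  z0 <- dem + eval_height
  veg_w <- 1 - veg$lw_transmissivity

  svf_sum <- matrix(0, nr, nc)
  for (d in seq_len(n_dirs)) {
    az <- 2 * pi * (d - 1) / n_dirs
    tan_b <- matrix(0, nr, nc)   # building horizon tangent
    tan_t <- matrix(0, nr, nc)   # building + vegetation horizon tangent
    for (k in seq_len(k_cap)) {
      dr <- -round(k * cos(az)); dc <- round(k * sin(az))
      if (abs(dr) >= nr && abs(dc) >= nc) break
      dist <- k * cell
      dsm_s <- shift_matrix(dsm, dr, dc, fill = -Inf)
      tan_b <- pmax(tan_b, (dsm_s - z0) / dist)
      veg_s <- shift_matrix(dem + chm, dr, dc, fill = -Inf)
      chm_s <- shift_matrix(chm, dr, dc, fill = 0)
      veg_s[chm_s <= 0] <- -Inf
      tan_t <- pmax(tan_t, (pmax(dsm_s, veg_s) - z0) / dist)
    }
    cos2 <- function(tn) 1 / (1 + tn^2)   # cos^2(atan(tn))
    svf_sum <- svf_sum + veg_w * cos2(tan_t) + (1 - veg_w) * cos2(tan_b)
  }
  pmin(pmax(svf_sum / n_dirs, 0), 1)
}
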