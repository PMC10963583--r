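#' Mean radiant flux density on the cylindrical person
#'
#' Absorption-weighted sum of the directional short- and long-wave fluxes:
#' `S_str = a_k * (w_up K_down + w_down K_up + 4 w_lat K_lat) +
#'  eps_p * (w_up L_down + w_down L_up + 4 w_lat L_lat)`.
#'
#' @param budget list with matrices (or scalars) `kdown`, `kup`, `klat`,
#'   `ldown`, `lup`, `llat`, all `>= 0` (W/m2); `klat`/`llat` are per lateral
#'   direction.
#' @param person a [person_model()].
#' @return matrix of mean radiant flux density (W/m2).
#' @export
mean_radiant_flux <- function(budget, person = person_model()) {
  comp <- budget[c("kdown", "kup", "klat", "ldown", "lup", "llat")]
  if (any(vapply(comp, function(x) any(x < 0), logical(1)))) {
    stop("radiation components must be >= 0", call. = FALSE)
  }
  ksum <- person$w_up * budget$kdown + person$w_down * budget$kup +
    4 * person$w_lateral * budget$klat
  lsum <- person$w_up * budget$ldown + person$w_down * budget$lup +
    4 * person$w_lateral * budget$llat
  person$sw_absorption * ksum + person$emissivity * lsum
}

#' Mean radiant temperature from mean radiant flux density
#'
#' `T_mrt = (S_str / (eps_p * sigma))^(1/4) - 273.15` with body emissivity
#' 0.97 and the Stefan-Boltzmann constant.
#'
#' @param sstr mean radiant flux density (W/m2), `>= 0`.
#' @param emissivity body emissivity.
#' @return mean radiant temperature (degC), same shape as `sstr`.
#' @export
tmrt_from_sstr <- function(sstr, emissivity = 0.97) {
  if (any(sstr < 0)) stop("sstr must be >= 0", call. = FALSE)
  (sstr / (emissivity * SIGMA_SB))^0.25 - 273.15
}

#' Mean radiant temperature grid for one timestamp
#'
#' Assembles the full radiation budget on the scene for one hour of
#' meteorology: shadow casting and the direct/diffuse split when the sun is
#' up (no shadow computation at night), longwave components always, then
#' `S_str` and `T_mrt` per cell.
#'
#' @param rasters a [site_rasters()].
#' @param svf sky-view-factor matrix for the scene (precompute with
#'   [sky_view_factor()]).
#' @param met one-row slice of a [met_series()] (or a list with `time`,
#'   `tair`, `rh`, `wind10`, `swdown`).
#' @param latitude,longitude site coordinates (deg).
#' @param params a [radiation_params()].
#' @return list with matrices `tmrt` (degC) and `sstr` (W/m2), the `shadow`
#'   result (or `NULL` at night) and the `budget` list.
#' @export
compute_tmrt_grid <- function(rasters, svf, met, latitude, longitude,
                              params = radiation_params()) {
  sun <- solar_position(met$time, latitude, longitude)
  zero <- matrix(0, nrow(rasters$dem), ncol(rasters$dem))
  shadow <- NULL
  if (sun$elevation > 0 && met$swdown > 0) {
    shadow <- cast_shadow(rasters, sun, params$veg,
                          trunk_ratio = params$trunk_ratio)
    sp <- split_direct_diffuse(met$swdown, sun)
    cosz <- cos(sun$zenith * pi / 180)
    sinz <- sin(sun$zenith * pi / 180)
    kdir_h <- sp$dni * cosz * shadow$factor
    kdown <- kdir_h + sp$dhi * svf
    kup <- params$ground_albedo * kdown
    klat <- 0.5 * (shadow$factor * sp$dni * sinz + 0.5 * (sp$dhi * svf + kup))
    shadow_factor <- shadow$factor
  } else {
    kdown <- kup <- klat <- zero
    shadow_factor <- 1
  }
  lw <- longwave_components(met$tair, met$rh, met$swdown, svf, sun, params,
                            shadow_factor = shadow_factor)
  budget <- list(kdown = kdown, kup = kup, klat = klat,
                 ldown = lw$ldown, lup = lw$lup, llat = lw$llat)
  sstr <- mean_radiant_flux(budget, params$person)
  list(tmrt = tmrt_from_sstr(sstr, params$person$emissivity),
       sstr = sstr, shadow = shadow, budget = budget)
}

# Tile index windows: list of (core rows/cols within site, buffered rows/cols,
# and the core's position inside the buffered window).
tile_windows <- function(nr, nc, tile_cells, buffer_cells) {
  splits <- function(n) {
    starts <- seq(1, n, by = tile_cells)
    lapply(starts, function(s) c(s, min(s + tile_cells - 1, n)))
  }
  wins <- list()
  for (rs in splits(nr)) for (cs in splits(nc)) {
    br <- c(max(1, rs[1] - buffer_cells), min(nr, rs[2] + buffer_cells))
    bc <- c(max(1, cs[1] - buffer_cells), min(nc, cs[2] + buffer_cells))
    wins[[length(wins) + 1]] <- list(
      core_rows = rs[1]:rs[2], core_cols = cs[1]:cs[2],
      buf_rows = br[1]:br[2], buf_cols = bc[1]:bc[2],
      inner_rows = (rs[1] - br[1] + 1):(rs[2] - br[1] + 1),
      inner_cols = (cs[1] - bc[1] + 1):(cs[2] - bc[1] + 1))
  }
  wins
}

#' Tiled mean radiant temperature over a site and met series
#'
#' Splits the site into square tiles, evaluates each tile on a buffered
#' window (so shadows cast into the tile from surrounding features are
#' captured), crops the core and concatenates. With a buffer at least as long
#' as the longest shadow and the SVF search distance, the result is
#' independent of the tiling.
#'
#' @param rasters a [site_rasters()] covering the full site.
#' @param met a [met_series()].
#' @param tile tile edge length (m).
#' @param buffer buffer width (m); must be at least one cell.
#' @param params a [radiation_params()].
#' @param reduce optional `function(tmrt_matrix, time_index)` called per
#'   timestamp instead of storing the full array (its returned values are
#'   collected in a list).
#' @return if `reduce` is `NULL`, a 3-d array `[time, row, col]` of T_mrt
#'   (degC); otherwise the list of `reduce` results.
#' @export
run_tiled <- function(rasters, met, tile = 50, buffer = 50,
                      params = radiation_params(), reduce = NULL) {
  cell <- rasters$cell_size
  if (buffer < cell) stop("buffer must be at least one cell", call. = FALSE)
  if (tile <= 0) stop("tile must be > 0", call. = FALSE)
  nr <- nrow(rasters$dem); nc <- ncol(rasters$dem)
  wins <- tile_windows(nr, nc, round(tile / cell), round(buffer / cell))
  lat <- attr(met, "latitude"); lon <- attr(met, "longitude")
  nt <- nrow(met)

  tiles <- lapply(wins, function(w) {
    r <- crop_rasters(rasters, w$buf_rows, w$buf_cols)
    svf <- sky_view_factor(r, n_dirs = params$svf_dirs,
                           max_dist = params$svf_max_dist, veg = params$veg)
    list(w = w, rasters = r, svf = svf)
  })

  out <- if (is.null(reduce)) array(NA_real_, c(nt, nr, nc)) else vector("list", nt)
  full <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nt)) {
    mi <- list(time = met$time[i], tair = met$tair[i], rh = met$rh[i],
               wind10 = met$wind10[i], swdown = met$swdown[i])
    for (tl in tiles) {
      g <- compute_tmrt_grid(tl$rasters, tl$svf, mi, lat, lon, params)
      full[tl$w$core_rows, tl$w$core_cols] <-
        g$tmrt[tl$w$inner_rows, tl$w$inner_cols]
    }
    if (is.null(reduce)) out[i, , ] <- full else out[[i]] <- reduce(full, i)
  }
  out
}
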