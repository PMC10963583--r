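#' Vegetation radiative parameters
#'
#' Defaults follow the standard evergreen-canopy values used in SOLWEIG-type
#' models: 3% shortwave and 0% longwave transmission through foliage, 15%
#' albedo, 90% emissivity.
#'
#' @param sw_transmissivity,lw_transmissivity,albedo,emissivity all in `[0, 1]`.
#' @return object of class `veg_params`.
#' @export
veg_params <- function(sw_transmissivity = 0.03, lw_transmissivity = 0.0,
                       albedo = 0.15, emissivity = 0.90) {
  v <- c(sw_transmissivity, lw_transmissivity, albedo, emissivity)
  if (any(v < 0 | v > 1)) stop("vegetation parameters must lie in [0, 1]", call. = FALSE)
  structure(list(sw_transmissivity = sw_transmissivity,
                 lw_transmissivity = lw_transmissivity,
                 albedo = albedo, emissivity = emissivity),
            class = "veg_params")
}

#' Cylindrical person model
#'
#' Directional view weights of a standing cylinder (up 0.06, down 0.06, four
#' lateral 0.22) which sum to one; body longwave emissivity 0.97; shortwave
#' absorption coefficient 0.70; evaluation height 1.5 m.
#'
#' @param emissivity body longwave emissivity.
#' @param sw_absorption shortwave absorption coefficient.
#' @param height evaluation height above ground (m).
#' @param w_up,w_down,w_lateral view weights (four lateral directions each
#'   carry `w_lateral`); must sum to 1.
#' @return object of class `person_model`.
#' @export
person_model <- function(emissivity = 0.97, sw_absorption = 0.70, height = 1.5,
                         w_up = 0.06, w_down = 0.06, w_lateral = 0.22) {
  if (abs(w_up + w_down + 4 * w_lateral - 1) > 1e-9) {
    stop("view weights must sum to 1", call. = FALSE)
  }
  structure(list(emissivity = emissivity, sw_absorption = sw_absorption,
                 height = height, w_up = w_up, w_down = w_down,
                 w_lateral = w_lateral),
            class = "person_model")
}

#' Radiation-model parameters
#'
#' @param veg a [veg_params()].
#' @param person a [person_model()].
#' @param ground_albedo shortwave albedo of the ground (paved default 0.20).
#' @param surface_emissivity longwave emissivity of built/ground surfaces.
#' @param surface_warming sunlit-surface warming coefficient (degC): surface
#'   temperature is `tair + surface_warming * K_cell / K_clear_max`, where
#'   `K_cell` is the shortwave reaching the cell and `K_clear_max` the
#'   zenith-sun clear-sky ceiling.
#' @param trunk_ratio fraction of canopy height below the crown (trunk zone).
#' @param svf_dirs azimuthal search directions for the sky view factor.
#' @param svf_max_dist horizon search distance (m) for the sky view factor.
#' @return object of class `radiation_params`.
#' @export
radiation_params <- function(veg = veg_params(), person = person_model(),
                             ground_albedo = 0.20, surface_emissivity = 0.95,
                             surface_warming = 15, trunk_ratio = 0.25,
                             svf_dirs = 48, svf_max_dist = 50) {
  structure(list(veg = veg, person = person, ground_albedo = ground_albedo,
                 surface_emissivity = surface_emissivity,
                 surface_warming = surface_warming, trunk_ratio = trunk_ratio,
                 svf_dirs = svf_dirs, svf_max_dist = svf_max_dist),
            class = "radiation_params")
}

# Clear-sky ceiling used to normalise the surface-warming term (W/m2).
CSKY_MAX <- SOLAR_CONSTANT * 0.7
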