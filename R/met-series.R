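#' Hourly meteorological series for the four UTCI drivers
#'
#' A `met_series` is a data frame with a strictly hourly POSIXct `time` column
#' (fixed-offset local standard time) and the four driver variables:
#' `tair` (air temperature, degC), `rh` (relative humidity, %), `wind10`
#' (10 m wind speed, m/s) and `swdown` (downwelling shortwave, W/m2).
#'
#' @param time POSIXct vector, strictly increasing at 1 h steps.
#' @param tair,rh,wind10,swdown numeric vectors of the same length.
#' @param latitude,longitude site coordinates in degrees (south/west negative).
#' @return An object of class `met_series` (a data frame).
#' @export
met_series <- function(time, tair, rh, wind10, swdown,
                       latitude = -42.883, longitude = 147.330) {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct", call. = FALSE)
  n <- length(time)
  for (v in list(tair, rh, wind10, swdown)) {
    if (length(v) != n) stop("all variables must match length(time)", call. = FALSE)
    if (any(!is.finite(v))) stop("non-finite values in met series", call. = FALSE)
  }
  dt <- diff(as.numeric(time))
  if (n > 1 && (any(dt != 3600))) {
    stop("timestamps must be strictly increasing at 1 h steps", call. = FALSE)
  }
  if (any(rh < 0 | rh > 100)) stop("rh must lie in [0, 100]", call. = FALSE)
  if (any(wind10 < 0)) stop("wind10 must be >= 0", call. = FALSE)
  if (any(swdown < 0)) stop("swdown must be >= 0", call. = FALSE)
  x <- data.frame(time = time, tair = tair, rh = rh,
                  wind10 = wind10, swdown = swdown)
  attr(x, "latitude") <- latitude
  attr(x, "longitude") <- longitude
  class(x) <- c("met_series", "data.frame")
  x
}

#' @export
print.met_series <- function(x, ...) {
  cat(sprintf("<met_series> %d hourly records, %s .. %s (lat %.3f, lon %.3f)\n",
              nrow(x), format(x$time[1]), format(x$time[nrow(x)]),
              attr(x, "latitude"), attr(x, "longitude")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Extract the variable matrix of a met series
#'
#' @param x a `met_series`.
#' @return numeric matrix with columns `tair`, `rh`, `wind10`, `swdown`.
#' @export
met_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, MET_VARS])
  rownames(m) <- NULL
  m
}

# Replace the variable columns of a met_series, revalidating bounds.
met_replace <- function(x, m) {
  met_series(x$time, m[, "tair"], m[, "rh"], m[, "wind10"], m[, "swdown"],
             latitude = attr(x, "latitude"), longitude = attr(x, "longitude"))
}
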