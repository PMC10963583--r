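#' Heat-map of an hour-by-day-of-year field
#'
#' Minimal plotting helper for fields from [change_by_hour_doy()] or
#' [median_as_historic_percentile()]. Requires ggplot2.
#'
#' @param field 24 x 365 matrix (hours by day of year).
#' @param title plot title.
#' @param legend legend label.
#' @return a ggplot object.
#' @export
plot_hour_doy_field <- function(field, title = "", legend = "value") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(hour = rep(0:23, times = 365),
                   doy = rep(1:365, each = 24),
                   value = as.vector(field))
  ggplot2::ggplot(df, ggplot2::aes(x = doy, y = hour, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = legend) +
    ggplot2::labs(x = "day of year", y = "hour of day", title = title) +
    ggplot2::theme_minimal()
}
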