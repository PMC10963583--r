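#' Assign hourly timestamps to (hour, block) time groups
#'
#' Bias correction operates within time-of-year groups. In `weekly` mode the
#' block is the ISO week of year with week 53 merged into week 52 (24 x 52
#' groups); in `daily` mode it is the day of year on a fixed 365-day calendar
#' with Feb 29 merged into Feb 28 (24 x 365 groups).
#'
#' @param time POSIXct vector at strict 1 h spacing.
#' @param mode `"weekly"` or `"daily"`.
#' @return data frame with integer columns `hour` (0-23), `block`, and a
#'   character `key` (`"hour.block"`), one row per timestamp.
#' @export
build_time_groups <- function(time, mode = c("weekly", "daily")) {
  mode <- match.arg(mode)
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct", call. = FALSE)
  if (length(time) > 1 && any(diff(as.numeric(time)) != 3600)) {
    stop("timestamps must be hourly", call. = FALSE)
  }
  lt <- as.POSIXlt(time)
  hour <- lt$hour
  if (mode == "weekly") {
    block <- as.integer(format(time, "%V"))
    block[block == 53] <- 52L
  } else {
    cum <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
    mon <- lt$mon + 1L
    mday <- lt$mday
    mday[mon == 2L & mday == 29L] <- 28L
    block <- cum[mon] + mday
  }
  data.frame(hour = hour, block = block,
             key = paste(hour, block, sep = "."),
             stringsAsFactors = FALSE)
}
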