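#' Write / read a met series as CSV
#'
#' Plain CSV with ISO timestamps; latitude, longitude and time zone are
#' stored in `#key=value` header comments so the round trip is lossless.
#'
#' @param x a [met_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_met_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tz <- attr(x$time, "tzone")
  writeLines(c(sprintf("#latitude=%.6f", attr(x, "latitude")),
               sprintf("#longitude=%.6f", attr(x, "longitude")),
               sprintf("#tz=%s", tz[1])), con)
  df <- as.data.frame(x)
  df$time <- format(df$time, "%Y-%m-%d %H:%M:%S")
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_met_csv
#' @return for `read_met_csv`, the reconstructed [met_series()].
#' @export
read_met_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  met_series(as.POSIXct(df$time, tz = meta[["tz"]]),
             df$tair, df$rh, df$wind10, df$swdown,
             latitude = as.numeric(meta[["latitude"]]),
             longitude = as.numeric(meta[["longitude"]]))
}

#' Write / read a raster layer as an ESRI ASCII grid
#'
#' Row 1 of the matrix is the northern edge, matching the format's top-down
#' row order.
#'
#' @param m numeric matrix.
#' @param path output file (`.asc`).
#' @param cell_size cell edge length (m).
#' @param xll,yll lower-left corner coordinates.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cell_size = 1, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %.6f", xll),
               sprintf("yllcorner %.6f", yll),
               sprintf("cellsize %.6f", cell_size),
               "NODATA_value -9999"), con)
  mm <- m
  mm[is.na(mm)] <- -9999
  write.table(format(mm, trim = TRUE, digits = 10), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return for `read_ascii_grid`, the matrix with attributes `cell_size`,
#'   `xll`, `yll`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  val <- function(k) {
    line <- hdr[grepl(paste0("^", k, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(line), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  nodata <- val("NODATA_value")
  v <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(v, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA
  attr(m, "cell_size") <- val("cellsize")
  attr(m, "xll") <- val("xllcorner")
  attr(m, "yll") <- val("yllcorner")
  m
}

#' Write / read a raster stack (DEM, DSM, CHM) as ASCII grids
#'
#' @param r a [site_rasters()].
#' @param dir directory for `dem.asc`, `dsm.asc`, `chm.asc`.
#' @return `dir` (or the [site_rasters()] on read), invisibly.
#' @export
write_site_rasters <- function(r, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (layer in c("dem", "dsm", "chm")) {
    write_ascii_grid(r[[layer]], file.path(dir, paste0(layer, ".asc")),
                     cell_size = r$cell_size)
  }
  invisible(dir)
}

#' @rdname write_site_rasters
#' @export
read_site_rasters <- function(dir) {
  g <- lapply(c("dem", "dsm", "chm"), function(layer) {
    read_ascii_grid(file.path(dir, paste0(layer, ".asc")))
  })
  site_rasters(g[[1]], g[[2]], g[[3]], cell_size = attr(g[[1]], "cell_size"))
}
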