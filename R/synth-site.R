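#' Specify a toy urban scene
#'
#' Flat (or gently varying) ground with box buildings and parabolic tree
#' crowns, used to exercise the radiation model without lidar inputs.
#'
#' @param extent length-2 numeric, site size in metres (x, y).
#' @param buildings list of buildings; each is a list with `footprint` (an
#'   n x 2 polygon matrix of x/y metres, or a length-4 vector
#'   `c(xmin, xmax, ymin, ymax)`) and `height` (m, > 0).
#' @param trees list of trees; each is a list with `centre` `c(x, y)` m,
#'   `crown_radius` m, `crown_top` m and `trunk_height` m.
#' @param ground_elev constant ground elevation (m) or a function
#'   `f(x, y)` returning elevations.
#' @return object of class `site_spec`.
#' @export
site_spec <- function(extent = c(150, 150), buildings = list(), trees = list(),
                      ground_elev = 0) {
  for (b in buildings) {
    if (is.null(b$height) || b$height <= 0) stop("building heights must be > 0", call. = FALSE)
  }
  for (tr in trees) {
    if (tr$crown_top <= 0 || tr$crown_radius <= 0) stop("tree dimensions must be > 0", call. = FALSE)
    if (tr$trunk_height < 0 || tr$trunk_height >= tr$crown_top) {
      stop("trunk_height must lie in [0, crown_top)", call. = FALSE)
    }
  }
  structure(list(extent = extent, buildings = buildings, trees = trees,
                 ground_elev = ground_elev),
            class = "site_spec")
}

footprint_matrix <- function(fp) {
  if (is.matrix(fp)) return(fp)
  if (length(fp) == 4) {
    return(cbind(c(fp[1], fp[2], fp[2], fp[1]), c(fp[3], fp[3], fp[4], fp[4])))
  }
  stop("footprint must be an n x 2 matrix or c(xmin, xmax, ymin, ymax)", call. = FALSE)
}

# Even-odd point-in-polygon test, vectorised over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise a toy scene to DEM/DSM/CHM grids
#'
#' Cells are squares indexed at their centres; row 1 is the northern edge.
#' `dsm - dem` equals the building height inside footprints and 0 elsewhere;
#' `chm` is the parabolic crown height inside crowns and 0 elsewhere.
#'
#' @param spec a [site_spec()].
#' @param cell_size cell edge length in metres (> 0).
#' @return object of class `site_rasters`: list with matrices `dem`, `dsm`,
#'   `chm` (rows north to south) and `cell_size`.
#' @export
gen_site_rasters <- function(spec, cell_size = 1) {
  stopifnot(inherits(spec, "site_spec"), cell_size > 0)
  nx <- round(spec$extent[1] / cell_size)
  ny <- round(spec$extent[2] / cell_size)
  xc <- (seq_len(nx) - 0.5) * cell_size
  yc <- rev((seq_len(ny) - 0.5) * cell_size)  # row 1 = north (max y)
  px <- rep(xc, each = ny)
  py <- rep(yc, times = nx)

  dem <- if (is.function(spec$ground_elev)) {
    matrix(spec$ground_elev(px, py), ny, nx)
  } else matrix(spec$ground_elev, ny, nx)

  bheight <- matrix(0, ny, nx)
  claimed <- matrix(FALSE, ny, nx)
  for (b in spec$buildings) {
    poly <- footprint_matrix(b$footprint)
    if (any(poly[, 1] < 0 | poly[, 1] > spec$extent[1] |
            poly[, 2] < 0 | poly[, 2] > spec$extent[2])) {
      stop("building footprint outside site extent", call. = FALSE)
    }
    inside <- matrix(point_in_polygon(px, py, poly), ny, nx)
    if (any(inside & claimed)) stop("overlapping building footprints", call. = FALSE)
    claimed <- claimed | inside
    bheight[inside] <- b$height
  }

  chm <- matrix(0, ny, nx)
  for (tr in spec$trees) {
    r <- sqrt((px - tr$centre[1])^2 + (py - tr$centre[2])^2)
    inside <- r <= tr$crown_radius
    h <- tr$trunk_height +
      (tr$crown_top - tr$trunk_height) * (1 - (r / tr$crown_radius)^2)
    hmat <- matrix(ifelse(inside, h, 0), ny, nx)
    chm <- pmax(chm, hmat)
  }

  site_rasters(dem = dem, dsm = dem + bheight, chm = chm, cell_size = cell_size)
}

#' Construct a validated raster stack
#'
#' @param dem,dsm,chm numeric matrices of identical shape (rows north to
#'   south): ground elevation, ground+building elevation, vegetation height.
#' @param cell_size cell edge length (m).
#' @return object of class `site_rasters`.
#' @export
site_rasters <- function(dem, dsm, chm, cell_size) {
  if (!all(dim(dem) == dim(dsm)) || !all(dim(dem) == dim(chm))) {
    stop("dem, dsm, chm must share dimensions", call. = FALSE)
  }
  if (any(dsm < dem - 1e-9)) stop("dsm must be >= dem everywhere", call. = FALSE)
  if (any(chm < 0)) stop("chm must be >= 0", call. = FALSE)
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  structure(list(dem = dem, dsm = dsm, chm = chm, cell_size = cell_size),
            class = "site_rasters")
}

#' @export
print.site_rasters <- function(x, ...) {
  cat(sprintf("<site_rasters> %d x %d cells at %.2f m; max building %.1f m, max canopy %.1f m\n",
              nrow(x$dem), ncol(x$dem), x$cell_size,
              max(x$dsm - x$dem), max(x$chm)))
  invisible(x)
}

# Crop a raster stack to row/col index ranges (used by the tiler).
crop_rasters <- function(r, rows, cols) {
  site_rasters(r$dem[rows, cols, drop = FALSE],
               r$dsm[rows, cols, drop = FALSE],
               r$chm[rows, cols, drop = FALSE],
               r$cell_size)
}
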