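# Shared fixtures built in code.

box_scene <- function(extent = c(40, 40), box = c(15, 25, 15, 25), height = 10,
                      trees = list(), cell = 1) {
  gen_site_rasters(site_spec(extent = extent,
                             buildings = list(list(footprint = box, height = height)),
                             trees = trees), cell)
}

# A mixed 60 x 60 m scene with two buildings and a tree.
mixed_scene <- function() {
  gen_site_rasters(site_spec(
    extent = c(60, 60),
    buildings = list(list(footprint = c(10, 20, 10, 20), height = 8),
                     list(footprint = c(35, 45, 30, 40), height = 12)),
    trees = list(list(centre = c(30, 50), crown_radius = 4, crown_top = 7,
                      trunk_height = 2))), 1)
}

random_scene <- function(n = 30, seed = 1) {
  set.seed(seed)
  nb <- sample(0:2, 1)
  bld <- lapply(seq_len(nb), function(i) {
    x0 <- runif(1, 2, n - 12); y0 <- runif(1, 2, n - 12)
    list(footprint = c(x0, x0 + runif(1, 3, 8), y0, y0 + runif(1, 3, 8)),
         height = runif(1, 3, 15))
  })
  # reject overlapping footprints by retrying with shifted seed
  spec <- tryCatch(
    site_spec(extent = c(n, n), buildings = bld,
              trees = if (runif(1) < 0.7) list(list(
                centre = runif(2, 5, n - 5), crown_radius = runif(1, 2, 4),
                crown_top = runif(1, 4, 10), trunk_height = runif(1, 0.5, 2)))
              else list()),
    error = function(e) NULL)
  r <- tryCatch(if (!is.null(spec)) gen_site_rasters(spec, 1) else NULL,
                error = function(e) NULL)
  if (is.null(r)) random_scene(n, seed + 1000) else r
}

hourly_times <- function(start, n, tz = "Etc/GMT-10") {
  seq(as.POSIXct(start, tz = tz), by = 3600, length.out = n)
}

flat_met <- function(times, tair = 20, rh = 50, wind = 3, swdown = 0) {
  met_series(times, rep_len(tair, length(times)), rep_len(rh, length(times)),
             rep_len(wind, length(times)), rep_len(swdown, length(times)))
}
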