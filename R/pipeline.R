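#' Build a pipeline run configuration
#'
#' Bundles the stage settings of a full run: synthetic generator, periods,
#' correction, radiation scene/tiling and stress thresholds. The
#' configuration is a plain nested list and can be round-tripped through
#' YAML (see [read_run_config()]).
#'
#' @param synth arguments for [synth_config()] (a named list), or a ready
#'   `synth_config`.
#' @param n_members ensemble members to simulate.
#' @param future_years length-2 integer vector for the projected period.
#' @param site a [site_spec()] or a directory containing `dem/dsm/chm.asc`.
#' @param cell_size raster cell size (m) when rasterising `site`.
#' @param tile,buffer tiling parameters (m).
#' @param correction a [correction_config()].
#' @param mbcn_mode MBCn time-group mode (`"daily"` or `"weekly"`).
#' @param radiation a [radiation_params()].
#' @param scale a [utci_stress_scale()].
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = list(), n_members = 1, future_years = NULL,
                       site = site_spec(extent = c(60, 60)), cell_size = 1,
                       tile = 50, buffer = 50,
                       correction = correction_config(), mbcn_mode = "daily",
                       radiation = radiation_params(),
                       scale = utci_stress_scale()) {
  cfg_synth <- if (inherits(synth, "synth_config")) synth else do.call(synth_config, synth)
  if (is.null(future_years)) {
    future_years <- c(cfg_synth$start_year, cfg_synth$end_year) + 50
  }
  if (future_years[1] <= cfg_synth$end_year) {
    stop("historic and future periods must not overlap", call. = FALSE)
  }
  structure(list(synth = cfg_synth, n_members = n_members,
                 future_years = future_years, site = site,
                 cell_size = cell_size, tile = tile, buffer = buffer,
                 correction = correction, mbcn_mode = mbcn_mode,
                 radiation = radiation, scale = scale),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()]; the
#' `synth`, `correction` and `radiation` blocks are passed to their
#' constructors. Buildings/trees under `site` follow [site_spec()].
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) {
    s <- y$synth
    for (nm in c("mean", "diurnal_amp", "annual_amp", "diurnal_phase",
                 "annual_phase", "ar1", "noise_sd")) {
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    }
    if (!is.null(s$cross_cor)) s$cross_cor <- do.call(rbind, s$cross_cor)
    args$synth <- s
  }
  for (nm in c("n_members", "future_years", "cell_size", "tile", "buffer",
               "mbcn_mode")) {
    if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
  }
  if (!is.null(y$site)) {
    if (is.character(y$site)) {
      args$site <- y$site
    } else {
      args$site <- site_spec(
        extent = unlist(y$site$extent),
        buildings = lapply(y$site$buildings, function(b)
          list(footprint = unlist(b$footprint), height = b$height)),
        trees = lapply(y$site$trees, function(tr)
          list(centre = unlist(tr$centre), crown_radius = tr$crown_radius,
               crown_top = tr$crown_top, trunk_height = tr$trunk_height)))
    }
  }
  if (!is.null(y$correction)) args$correction <- do.call(correction_config, y$correction)
  do.call(run_config, args)
}

# Stable md5 of an R object via its serialised JSON representation.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, force = TRUE, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full projection pipeline on synthetic data
#'
#' Stages: simulate (reference + ensemble members), correct (grouped QDM then
#' MBCn), radiate (tiled mean radiant temperature over the scene, reduced to
#' per-timestamp site extremes), UTCI + stress classification, summarise.
#' Intermediates and tables are written under `out_dir` together with a run
#' manifest (config hash, per-file checksums, warnings); identical
#' configuration and seed reproduce identical checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param seed integer master seed for all stochastic stages.
#' @return the manifest (list), invisibly; see files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(config$site)) {
    if (!dir.exists(config$site)) {
      stop(sprintf("config error: raster directory '%s' not found", config$site),
           call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  ## stage 1: simulate
  ref <- gen_reference_series(config$synth, seed)
  write_met_csv(ref, file.path(out_dir, "reference.csv"))
  member_seeds <- withr_seed(seed, sample.int(2^31 - 2, config$n_members))
  members <- lapply(member_seeds, function(s) {
    gen_model_pair(config$synth, s, future_years = config$future_years)
  })

  ## stage 2: correct
  corrected <- vector("list", length(members))
  for (i in seq_along(members)) {
    corrected[[i]] <- withCallingHandlers(
      correct_met_pair(ref, members[[i]]$historical, members[[i]]$future,
                       config = config$correction, mbcn_mode = config$mbcn_mode),
      warning = function(w) {
        note("member %d correction: %s", i, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    write_met_csv(corrected[[i]]$historical,
                  file.path(out_dir, sprintf("member%02d_hist.csv", i)))
    write_met_csv(corrected[[i]]$future,
                  file.path(out_dir, sprintf("member%02d_fut.csv", i)))
  }

  ## stage 3+4: radiate and UTCI site extremes
  rasters <- if (is.character(config$site)) {
    read_site_rasters(config$site)
  } else {
    gen_site_rasters(config$site, config$cell_size)
  }
  write_site_rasters(rasters, file.path(out_dir, "rasters"))

  extremes <- lapply(corrected, function(mem) {
    lapply(mem[c("historical", "future")], function(ms) {
      tm <- run_tiled(rasters, ms, tile = config$tile, buffer = config$buffer,
                      params = config$radiation,
                      reduce = function(g, i) c(min(g), mean(g), max(g)))
      tm <- do.call(rbind, tm)
      u_max <- as.numeric(utci(ms$tair, tm[, 3], ms$wind10, ms$rh))
      u_min <- as.numeric(utci(ms$tair, tm[, 1], ms$wind10, ms$rh))
      u_mean <- as.numeric(utci(ms$tair, tm[, 2], ms$wind10, ms$rh))
      data.frame(time = ms$time, tmrt_min = tm[, 1], tmrt_mean = tm[, 2],
                 tmrt_max = tm[, 3], utci_min = u_min, utci_mean = u_mean,
                 utci_max = u_max)
    })
  })
  for (i in seq_along(extremes)) {
    for (per in c("historical", "future")) {
      df <- extremes[[i]][[per]]
      df$time <- format(df$time, "%Y-%m-%d %H:%M:%S")
      tag <- c(historical = "hist", future = "fut")[[per]]
      write.csv(df, file.path(out_dir, sprintf("member%02d_%s_extremes.csv", i, tag)),
                row.names = FALSE, quote = FALSE)
    }
  }

  ## stage 5: summarise (ensemble pooled)
  pool <- function(per) {
    list(met = do.call(rbind, lapply(corrected, function(m) as.data.frame(m[[per]]))),
         ext = do.call(rbind, lapply(extremes, function(e) e[[per]])))
  }
  ph <- pool("historical"); pf <- pool("future")
  tab <- summary_table(ph$met, pf$met, ph$ext, pf$ext,
                       hist_utci = ph$ext$utci_mean, fut_utci = pf$ext$utci_mean,
                       scale = config$scale)
  write.csv(tab$means, file.path(out_dir, "summary_means.csv"), row.names = FALSE)
  write.csv(tab$stress, file.path(out_dir, "summary_stress.csv"), row.names = FALSE)

  ## manifest
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  checksums <- tools::md5sum(sort(files))
  names(checksums) <- substring(names(checksums), nchar(out_dir) + 2)
  manifest <- list(
    package_version = as.character(utils::packageVersion("heatscape")),
    seed = seed,
    config_hash = object_hash(unclass_deep(config)),
    member_seeds = member_seeds,
    checksums = as.list(checksums),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Strip classes/functions so a config can be hashed as data.
unclass_deep <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  unclass(x)
}
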