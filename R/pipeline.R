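# End-to-end pipeline: simulate -> classify -> times -> counts -> model.
#
# Each stage writes its artifacts under the output directory and records a
# parameter hash in the manifest; a rerun reuses a stage's on-disk outputs
# when its parameters (and upstream hashes) are unchanged.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with the stated defaults: walking
#' 5 km/h, cycling 14 km/h, at most 2 bus transfers, 30-minute access/egress
#' walks, 5-minute waits, a 10:00--16:00 service window, 20/30-minute
#' accessibility thresholds, 99% confidence level with the most affluent
#' quintile as baseline.
#'
#' @param region a [region_config()].
#' @param modes transport modes to route, default all four.
#' @param bus a [bus_config()].
#' @param analysis an [analysis_config()].
#' @param level confidence level for model rate ratios, default 0.99.
#' @param n_permutations Moran permutation count, default 199.
#' @param include_light keep light-intensity facilities in counts
#'   (default FALSE: they are classified but excluded).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(region = region_config(),
                            modes = c("walk", "cycle", "car", "bus"),
                            bus = bus_config(),
                            analysis = analysis_config(),
                            level = 0.99, n_permutations = 199,
                            include_light = FALSE) {
  stopifnot(inherits(region, "region_config"), inherits(bus, "bus_config"),
            inherits(analysis, "analysis_config"),
            all(modes %in% c("walk", "cycle", "car", "bus")))
  if (include_light) {
    analysis$intensities <- union(analysis$intensities, "light")
  }
  structure(list(region = region, modes = modes, bus = bus,
                 analysis = analysis, level = level,
                 n_permutations = n_permutations,
                 include_light = include_light),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Any omitted field falls back to the package default. Recognised top-level
#' keys: `region` (fields of [region_config()]), `modes`, `bus` (fields of
#' [bus_config()]), `analysis` (fields of [analysis_config()]), `level`,
#' `n_permutations`, `include_light`.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the region config's.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  rc <- do.call(region_config, y$region %||% list())
  if (!is.null(seed)) {
    args <- unclass(rc)
    args$seed <- as.integer(seed)
    rc <- do.call(region_config, args)
  }
  pipeline_config(
    region = rc,
    modes = y$modes %||% c("walk", "cycle", "car", "bus"),
    bus = do.call(bus_config, y$bus %||% list()),
    analysis = do.call(analysis_config, y$analysis %||% list()),
    level = y$level %||% 0.99,
    n_permutations = y$n_permutations %||% 199,
    include_light = isTRUE(y$include_light))
}

.stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[modaccess] ", fmt), ...))
}

.manifest_read <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::fromJSON(p, simplifyVector = FALSE) else NULL
}

#' Run the full accessibility pipeline
#'
#' Executes simulate, classify, times (one travel-time matrix per mode),
#' counts and model stages in order, writing every artifact plus a manifest
#' of file hashes, seeds and stage parameter hashes to `out_dir`. When
#' `resume = TRUE` a stage whose parameter hash matches the previous
#' manifest and whose outputs exist is reloaded from disk instead of rerun.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param resume reuse unchanged stage outputs, default TRUE.
#' @param quiet suppress stage log messages.
#' @return the manifest (list), invisibly; artifacts on disk include
#'   `model_results.csv` and `quintile_summary.csv`.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prev <- if (resume) .manifest_read(out_dir) else NULL
  manifest <- list(package_version =
                     as.character(utils::packageVersion("modaccess")),
                   seed = config$region$seed, stages = list(), files = list())
  t_all <- Sys.time()

  stage_done <- function(name, hash, files) {
    manifest$stages[[name]] <<- list(hash = hash, files = files)
    for (f in files) {
      manifest$files[[f]] <<- unname(tools::md5sum(file.path(out_dir, f)))
    }
  }
  stage_fresh <- function(name, hash, files) {
    !is.null(prev) &&
      identical(prev$stages[[name]]$hash, hash) &&
      all(file.exists(file.path(out_dir, files)))
  }
  run_stage <- function(name, hash, files, produce) {
    t0 <- Sys.time()
    if (stage_fresh(name, hash, files)) {
      .stage_log(quiet, "%s: reused (%s)", name, hash)
    } else {
      ok <- tryCatch({ produce(); TRUE }, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE)
      })
      .stage_log(quiet, "%s: done in %.1fs", name,
                 as.numeric(Sys.time() - t0, units = "secs"))
    }
    stage_done(name, hash, files)
  }

  # simulate
  region_dir <- file.path(out_dir, "region")
  h_sim <- md5_of(unclass(config$region))
  sim_files <- file.path("region",
                         c("network.geojson", "zones.geojson", "zones.csv",
                           "facilities.csv", "adjacency.csv", "truth.json",
                           file.path("gtfs", c("stops.txt", "routes.txt",
                                               "trips.txt", "stop_times.txt",
                                               "route_stops.txt"))))
  run_stage("simulate", h_sim, sim_files, function() {
    bundle <- generate_region(config$region)
    write_region(bundle, region_dir)
  })
  bundle <- read_region(region_dir)

  # classify
  h_cls <- md5_of(list(h_sim, "classify"))
  run_stage("classify", h_cls, "facilities_classified.csv", function() {
    cls <- classify_facilities(bundle$facilities)
    write.csv(cls, file.path(out_dir, "facilities_classified.csv"),
              row.names = FALSE)
  })
  facilities <- read.csv(file.path(out_dir, "facilities_classified.csv"),
                         stringsAsFactors = FALSE)

  # times: one matrix per mode
  zones_pts <- bundle$zones[, c("zone_id", "x", "y")]
  fac_pts <- facilities[, c("facility_id", "x", "y")]
  time_files <- sprintf("times_%s.csv", config$modes)
  for (k in seq_along(config$modes)) {
    m <- config$modes[k]
    h_t <- md5_of(list(h_sim, h_cls, m,
                       if (m == "bus") unclass(config$bus)))
    run_stage(paste0("times_", m), h_t, time_files[k], function() {
      mg <- build_mode_graph(bundle$network, mode_config(m))
      ttm <- travel_time_matrix(m, mg, zones_pts, fac_pts,
                                timetable = bundle$timetable,
                                bus_cfg = config$bus)
      write.csv(ttm, file.path(out_dir, time_files[k]), row.names = FALSE)
    })
  }
  ttms <- lapply(time_files, function(f) {
    d <- read.csv(file.path(out_dir, f), stringsAsFactors = FALSE)
    class(d) <- c("travel_time_matrix", "data.frame")
    d
  })

  # counts
  h_cnt <- md5_of(list(vapply(paste0("times_", config$modes),
                              function(s) manifest$stages[[s]]$hash, ""),
                       unclass(config$analysis)))
  run_stage("counts", h_cnt,
            c("accessibility.csv", "quintile_summary.csv"), function() {
    acc <- accessibility_table(ttms, facilities, bundle$zones,
                               config$analysis)
    write.csv(acc, file.path(out_dir, "accessibility.csv"), row.names = FALSE)
    write.csv(quintile_summary(acc, bundle$zones),
              file.path(out_dir, "quintile_summary.csv"), row.names = FALSE)
  })
  acc <- read.csv(file.path(out_dir, "accessibility.csv"),
                  stringsAsFactors = FALSE)
  class(acc) <- c("accessibility_table", "data.frame")

  # model
  h_mod <- md5_of(list(h_cnt, config$level, config$n_permutations))
  run_stage("model", h_mod,
            c("model_results.csv", "model_skipped.csv"), function() {
    fit <- stratified_analysis(acc, bundle$zones, bundle$adjacency,
                               level = config$level,
                               n_permutations = config$n_permutations,
                               seed = config$region$seed)
    write.csv(fit$results, file.path(out_dir, "model_results.csv"),
              row.names = FALSE)
    write.csv(fit$skipped, file.path(out_dir, "model_skipped.csv"),
              row.names = FALSE)
  })

  .stage_log(quiet, "pipeline complete in %.1fs",
             as.numeric(Sys.time() - t_all, units = "secs"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
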