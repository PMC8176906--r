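# End-to-end pipeline: terrain -> typology -> survey/matrix -> LCV ->
# susceptibility, with YAML configuration and a JSON run manifest.

#' Default pipeline configuration
#'
#' A nested list mirroring the YAML config schema. Paths under `inputs` may be
#' `NULL`, in which case the synthetic generators supply the corresponding
#' input (seeded from `seed`). `nulm` entries override the data-driven
#' threshold defaults; `weights` overrides the importance factors.
#'
#' @param output_dir directory for stage outputs and the manifest.
#' @param seed master seed; stage seeds are derived as small offsets.
#' @return a list of class `lcv_config`.
#' @export
default_config <- function(output_dir = tempfile("lcvmap_run_"), seed = 7L) {
  structure(list(
    output_dir = output_dir,
    seed = as.integer(seed),
    inputs = list(dem = NULL, landcover = NULL, zones = NULL,
                  survey = NULL, matrix = NULL),
    island = list(rows = 64L, cols = 64L, cell_size = 30),
    n_zones = 3L,
    flow_method = "mfd",
    nulm = list(),
    weights = list(),
    focal_window = 3L,
    susceptibility_percentile = 80
  ), class = "lcv_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return a list of class `lcv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      for (kk in names(user[[k]])) cfg[[k]][[kk]] <- user[[k]][[kk]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  p <- cfg$susceptibility_percentile
  if (p <= 0 || p >= 100) {
    stop("susceptibility_percentile must be in (0, 100)", call. = FALSE)
  }
  cfg
}

#' Run the full conservation-value pipeline
#'
#' Stage order: inputs (read or simulate) -> terrain derivatives and landform
#' classification -> landscape typology -> value matrix (from survey
#' responses, a matrix file, or the packaged reference matrix) -> LCV grid ->
#' zonal statistics -> focal-SD susceptibility mask. All stage outputs are
#' written under `config$output_dir` and checksummed into `manifest.json`;
#' re-running with the same config and seed reproduces identical checksums.
#'
#' @param config an `lcv_config` list (see [default_config()]) or the path to
#'   a YAML file.
#' @param verbose print stage progress messages.
#' @return the run manifest, invisibly: a list with the config snapshot,
#'   derived thresholds, and per-output md5 checksums.
#' @export
run_pipeline <- function(config = default_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...))
  out <- function(name) file.path(cfg$output_dir, name)

  stage <- "inputs"
  res <- tryCatch({
    say("[%s] preparing inputs", stage)
    dem <- if (!is.null(cfg$inputs$dem)) read_grid_asc(cfg$inputs$dem) else {
      gen_dem(island_params(
        grid_shape = c(cfg$island$rows, cfg$island$cols),
        cell_size = cfg$island$cell_size, seed = cfg$seed))
    }
    landcover <- if (!is.null(cfg$inputs$landcover)) {
      read_grid_asc(cfg$inputs$landcover)
    } else gen_landcover(dem, seed = cfg$seed + 1L)
    zoneset <- if (!is.null(cfg$inputs$zones)) {
      read_zones_geojson(cfg$inputs$zones)
    } else gen_zones(dem, n_zones = cfg$n_zones, seed = cfg$seed + 2L)
    write_grid_asc(dem, out("dem.asc"))
    write_grid_asc(landcover, out("landcover.asc"))
    write_zones_geojson(zoneset, out("zones.geojson"))

    stage <- "terrain"
    say("[%s] computing derivatives and classifying landforms", stage)
    derivs <- terrain_derivatives(dem, method = cfg$flow_method)
    th <- do.call(nulm_thresholds, c(list(derivs = derivs), cfg$nulm))
    landform <- remap_landform(classify_nulm(derivs, th))
    say("[%s] channel threshold %.1f m upslope area", stage,
        th$channel_upslope_min)
    write_grid_asc(landform, out("landform.asc"))

    stage <- "typology"
    say("[%s] overlaying landscape types", stage)
    types <- overlay_types(landform, landcover)
    type_table <- tabulate_type_areas(types)
    say("[%s] %d landscape types present", stage, nrow(type_table))
    write_grid_asc(types, out("types.asc"))
    write_type_areas_csv(type_table, out("type_areas.csv"))

    stage <- "survey"
    weights <- do.call(importance_weights, cfg$weights)
    lcv_m <- if (!is.null(cfg$inputs$matrix)) {
      say("[%s] loading value matrix from file", stage)
      read_matrix_csv(cfg$inputs$matrix)
    } else if (!is.null(cfg$inputs$survey)) {
      say("[%s] aggregating expert survey", stage)
      aggregate_survey(read_survey_csv(cfg$inputs$survey), weights)
    } else {
      say("[%s] aggregating simulated expert panel", stage)
      aggregate_survey(gen_survey(survey_sim_params(seed = cfg$seed + 3L)),
                       weights)
    }
    if (!isTRUE(attr(lcv_m, "normalized"))) lcv_m <- rescale_1_10(lcv_m)
    write_matrix_csv(lcv_m, out("lcv_matrix.csv"))

    stage <- "lcv"
    say("[%s] mapping conservation values", stage)
    lcv <- apply_lcv_matrix(types, lcv_m)
    write_grid_asc(lcv, out("lcv.asc"))
    zstats <- zonal_lcv_stats(lcv, zoneset)
    write_zonal_stats_csv(zstats, out("zonal_stats.csv"))

    stage <- "susceptibility"
    say("[%s] focal SD (window %d) and top-%g%% mask", stage,
        cfg$focal_window, 100 - cfg$susceptibility_percentile)
    fsd <- focal_sd(lcv, window = cfg$focal_window)
    susc <- susceptibility_mask(fsd, cfg$susceptibility_percentile)
    write_grid_asc(fsd, out("focal_sd.asc"))
    write_grid_asc(susc$mask, out("mask.asc"))
    say("[%s] threshold %.4f", stage, susc$threshold)
    susc
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  outputs <- c("dem.asc", "landcover.asc", "zones.geojson", "landform.asc",
               "types.asc", "type_areas.csv", "lcv_matrix.csv", "lcv.asc",
               "zonal_stats.csv", "focal_sd.asc", "mask.asc")
  checksums <- as.list(tools::md5sum(vapply(outputs, out, "")))
  names(checksums) <- outputs
  manifest <- list(
    package = "lcvmap",
    version = as.character(utils::packageVersion("lcvmap")),
    config = unclass(cfg)[setdiff(names(cfg), "output_dir")],
    susceptibility = list(percentile = res$percentile,
                          threshold = res$threshold),
    checksums = checksums
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
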