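#' Pipeline configuration
#'
#' Bundles every stage's parameters. The defaults reproduce the reference
#' parameterization of the acquisition platform: 5 plants per plate,
#' 19 um/px, 8 h timestep, detector thresholds s1 = 25 and s2 = 10 gray
#' levels, 2000 px minimum component size, and 25 x MADe artefact bounds.
#'
#' @param input_dir directory of TIFF frames (see [read_timeseries()]).
#' @param pattern frame file pattern.
#' @param out_dir output directory.
#' @param n_plants plants per plate.
#' @param px_size_um,timestep_h acquisition geometry.
#' @param s1,s2 segmentation thresholds, 8-bit gray levels.
#' @param min_component_px component-size filter.
#' @param register,dense run registration / add the dense correction.
#' @param seed_target_row seed-line row for upstream extrapolation
#'   (`NULL` disables).
#' @param register_cfg,tracking_cfg,geometry_cfg stage configurations.
#' @param exclusion_mask optional logical matrix; `TRUE` pixels are
#'   excluded from segmentation (e.g. fallen leaves, plate border).
#' @param seed RNG seed (the pipeline itself is deterministic; the seed is
#'   recorded for provenance).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, pattern = "\\.tif$",
                            out_dir = NULL, n_plants = 5,
                            px_size_um = 19, timestep_h = 8,
                            s1 = 25, s2 = 10, min_component_px = 2000,
                            register = TRUE, dense = FALSE,
                            seed_target_row = NULL,
                            register_cfg = register_config(),
                            tracking_cfg = tracking_config(),
                            geometry_cfg = geometry_config(),
                            exclusion_mask = NULL, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a resolved pipeline configuration as JSON
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- config
  cfg$exclusion_mask <- NULL
  cfg$register_cfg <- unclass(cfg$register_cfg)
  cfg$tracking_cfg <- unclass(cfg$tracking_cfg)
  cfg$geometry_cfg <- unclass(cfg$geometry_cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reconstruct the architecture from an apparition-time image
#'
#' Runs the tracking and geometry stages: region adjacency graph, primary
#' extraction, Edmonds spanning forest, crossing resolution, artefact
#' rejection, timed centerline model, then the seed and stopped-lateral
#' post-processes.
#'
#' @param S a filtered [apparition_image()].
#' @param n_plants seedlings on the plate.
#' @param tracking_cfg a [tracking_config()].
#' @param geometry_cfg a [geometry_config()].
#' @param last_frame intensity image of the last observation (needed for
#'   seed extrapolation; `NULL` skips it).
#' @return list with `model` ([root_system_model()]), `forest`, `graph`
#'   and a `log` tibble of stage counters.
#' @export
reconstruct_architecture <- function(S, n_plants,
                                     tracking_cfg = tracking_config(),
                                     geometry_cfg = geometry_config(),
                                     last_frame = NULL) {
  G <- build_rag(S)
  max_source_row <- if (!is.null(geometry_cfg$seed_target_row))
    geometry_cfg$seed_target_row + 0.2 * nrow(S) else NULL
  G <- extract_primaries(G, n_plants, max_source_row)
  forest <- prune_to_forest(G)
  ep0 <- forest_endpoints(forest)
  forest <- resolve_crossings(forest, G, tracking_cfg)
  forest <- reject_artefact_roots(forest, tracking_cfg)
  model <- build_model(forest, S, geometry_cfg)
  if (!is.null(geometry_cfg$seed_target_row) && !is.null(last_frame))
    model <- extrapolate_to_seed(model, last_frame,
                                 geometry_cfg$seed_target_row,
                                 geometry_cfg)
  model <- handle_stopped_laterals(model, forest, geometry_cfg)
  log <- tibble(
    stage = c("rag", "primaries", "forest", "crossing", "artefacts",
              "model"),
    vertices = nrow(G$vertices),
    edges = nrow(G$edges),
    starts = length(ep0$start),
    stops = length(ep0$stop),
    connected = attr(forest, "n_connected") %||% 0L,
    rejected = length(attr(forest, "rejected") %||% integer(0)),
    outliers_dropped = attr(G, "n_outliers_dropped") %||% 0L)
  list(model = model, forest = forest, graph = G, log = log)
}

#' Run the full pipeline on one plate
#'
#' registration -> 2D+t segmentation -> topological tracking ->
#' architecture reconstruction -> RSML and phene tables. Per-stage
#' artifacts are persisted under `out_dir` when it is set; the run is
#' fully deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param stack optionally, an in-memory [image_timeseries()] instead of
#'   `config$input_dir`.
#' @return list with `model`, `S`, `stack`, `log`, and the written paths.
#' @export
run_pipeline <- function(config = pipeline_config(), stack = NULL) {
  t0 <- Sys.time()
  if (is.null(stack)) {
    if (is.null(config$input_dir)) stop("no input: set input_dir")
    stack <- read_timeseries(config$input_dir, config$pattern,
                             config$timestep_h, config$px_size_um)
  }
  if (length(stack$frames) < 2) stop("needs >=2 observations")
  timing <- list()
  tic <- function() Sys.time()
  lap <- function(start) as.numeric(difftime(Sys.time(), start,
                                             units = "secs"))
  if (config$register && is.null(stack$transforms)) {
    tr <- tic()
    stack <- register_timeseries(stack, config$register_cfg,
                                 dense = config$dense)
    timing$register <- lap(tr)
  }
  ts <- tic()
  S <- suppressWarnings(segment_stack(stack, config$s1, config$s2))
  if (!is.null(config$exclusion_mask)) {
    S2 <- unclass(S)
    S2[config$exclusion_mask] <- 0L
    S <- apparition_image(S2, attr(S, "n_timesteps"),
                          attr(S, "px_size_um"), attr(S, "timestep_h"))
  }
  S <- filter_components(S, config$min_component_px)
  timing$segment <- lap(ts)
  tt <- tic()
  rec <- reconstruct_architecture(
    S, config$n_plants, config$tracking_cfg, config$geometry_cfg,
    last_frame = stack$frames[[length(stack$frames)]])
  timing$track_reconstruct <- lap(tt)
  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$rsml <- file.path(config$out_dir, "architecture.rsml")
    write_rsml(rec$model, paths$rsml)
    paths$phenes <- file.path(config$out_dir, "phenes.csv")
    utils::write.csv(phene_table(rec$model), paths$phenes,
                     row.names = FALSE)
    paths$labels <- file.path(config$out_dir, "apparition_labels.tif")
    write_tiff_gray(unclass(S), paths$labels, bits = 16)
    paths$config <- file.path(config$out_dir, "resolved_config.json")
    write_pipeline_config(config, paths$config)
    paths$log <- file.path(config$out_dir, "stage_log.csv")
    utils::write.csv(rec$log, paths$log, row.names = FALSE)
    if (!is.null(stack$transforms)) {
      paths$transforms <- file.path(config$out_dir, "transforms.json")
      write_transforms_json(stack$transforms, paths$transforms)
    }
  }
  rec$log$total_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(model = rec$model, S = S, stack = stack, forest = rec$forest,
       graph = rec$graph, log = rec$log, timing = timing, paths = paths)
}
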