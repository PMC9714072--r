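root_profile <- function(d, width_px, contrast) {
  # transverse intensity drop: flat dark core at the centerline, Gaussian
  # falloff toward the border ("low intensities" center, "medium" border)
  core <- 0.2 * width_px
  sigma <- 0.3 * width_px
  drop <- ifelse(d <= core, 1, exp(-(d - core)^2 / (2 * sigma^2)))
  contrast * drop
}

plate_static_features <- function(model, params) {
  # intensity drop image of the static plate content: dish border ring
  # and seed bodies
  shp <- params$image_shape
  px_mm <- params$px_size_um / 1000
  drop <- matrix(0, shp[1], shp[2])
  # the camera field extends beyond the dish: the dish border sits 8 mm
  # inside the image so that its corners are matchable anchors for
  # registration
  b0 <- max(3, round(8 / px_mm))
  bw <- max(2, round(0.8 / px_mm))
  ring <- c(b0:(b0 + bw - 1))
  drop[ring, ] <- 60
  drop[shp[1] - ring + 1, ] <- 60
  drop[, ring] <- 60
  drop[, shp[2] - ring + 1] <- 60
  seeds <- attr(model, "seeds_px")
  if (!is.null(seeds)) {
    r_seed <- 0.5 / px_mm
    for (i in seq_len(nrow(seeds))) {
      rr <- max(1, floor(seeds[i, "y"] - 3 * r_seed)):
        min(shp[1], ceiling(seeds[i, "y"] + 3 * r_seed))
      cc <- max(1, floor(seeds[i, "x"] - 3 * r_seed)):
        min(shp[2], ceiling(seeds[i, "x"] + 3 * r_seed))
      d2 <- outer((rr - seeds[i, "y"])^2, (cc - seeds[i, "x"])^2, "+")
      drop[rr, cc] <- pmax(drop[rr, cc],
                           90 * exp(-d2 / (2 * (r_seed / 1.2)^2)))
    }
  }
  drop
}

#' Rasterize a ground-truth model into an image time series
#'
#' Draws every organ as an anti-aliased tube (flat dark core plus Gaussian
#' falloff) on a light background. Frame `k` shows exactly the organ
#' portions whose passage time is `<= k`; pixel coverage is therefore
#' nested across frames. Per-frame rigid jitter and Gaussian sensor noise
#' are applied afterwards, and the applied jitter transforms are returned
#' so registration can be validated against them.
#'
#' @param model a [root_system_model()] (typically from
#'   [simulate_architecture()]).
#' @param params the [sim_params()] used to build the model.
#' @return an [image_timeseries()] with attributes:
#'   `jitter` (list of per-frame forward [rt_rigid()] transforms),
#'   `coverage_time` (matrix of first-coverage times, `Inf` off-root),
#'   `tube_dist` (distance to the nearest centerline sample), and
#'   `model` (the input model).
#' @export
rasterize_timeseries <- function(model, params) {
  shp <- params$image_shape
  organs <- model_organs(model)
  polys <- lapply(organs, function(e)
    cbind(e$organ$x, e$organ$y, e$organ$t))
  radius <- params$root_width_px / 2 + 1.2
  ras <- rasterize_polylines_cpp(polys, shp[1], shp[2], radius, 0.4)
  prof <- root_profile(ras$dist, params$root_width_px,
                       params$root_contrast)
  prof[!is.finite(prof)] <- 0
  # static plate features present in every frame: the dish border and the
  # seeds. They are what registration locks onto in the earliest frames
  # (radicles are still tiny), and being temporally constant they produce
  # no intensity drop, so segmentation ignores them.
  static_drop <- plate_static_features(model, params)
  set.seed(derive_seed(params$seed, 2))
  n_t <- params$n_timesteps
  jit <- vector("list", n_t)
  frames <- vector("list", n_t)
  center <- c((shp[2] + 1) / 2, (shp[1] + 1) / 2)
  has_jitter <- any(params$jitter > 0)
  for (k in seq_len(n_t)) {
    img <- matrix(params$background_level, shp[1], shp[2]) - static_drop
    cov <- ras$time <= k + 1e-9
    img[cov] <- pmin(img[cov], params$background_level - prof[cov])
    if (has_jitter) {
      jit[[k]] <- rt_rigid(
        theta = runif(1, -params$jitter[2], params$jitter[2]) * pi / 180,
        dx = runif(1, -params$jitter[1], params$jitter[1]),
        dy = runif(1, -params$jitter[1], params$jitter[1]),
        center = center)
      img <- resample(img, jit[[k]], fill = params$background_level)
    } else {
      jit[[k]] <- rt_rigid(center = center)
    }
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, params$noise_sd),
                          shp[1], shp[2])
    frames[[k]] <- clamp(round(img), 0, 255)
  }
  out <- image_timeseries(frames, params$timestep_h, params$px_size_um)
  attr(out, "jitter") <- jit
  attr(out, "coverage_time") <- ras$time
  attr(out, "tube_dist") <- ras$dist
  attr(out, "model") <- model
  out
}

#' Inject persistent condensation/dirt blobs into a time series
#'
#' Adds small dark blobs (below the component-size filter threshold of the
#' segmentation stage) that appear at a random frame and persist in all
#' later frames, emulating nightly condensation and dirt falling on the
#' dish. Deterministic given the params seed.
#'
#' @param stack an [image_timeseries()] from [rasterize_timeseries()].
#' @param params a [sim_params()]; `artifact_rate` is the expected number
#'   of new blobs per frame (0 leaves the stack unchanged).
#' @param area_range blob area range in pixels.
#' @return the stack with blobs added and a `blobs` attribute (tibble:
#'   frame, row, col, radius, depth) recording the injected ledger.
#' @export
inject_artifacts <- function(stack, params, area_range = c(60, 400)) {
  force(stack)    # must be fully built before the RNG stream is seeded
  if (params$artifact_rate <= 0) {
    attr(stack, "blobs") <- tibble(frame = integer(), row = numeric(),
                                   col = numeric(), radius = numeric(),
                                   depth = numeric())
    return(stack)
  }
  set.seed(derive_seed(params$seed, 3))
  shp <- dim(stack$frames[[1]])
  n_t <- length(stack$frames)
  blobs <- list()
  layer <- matrix(0, shp[1], shp[2])
  for (k in seq_len(n_t)) {
    n_new <- rpois(1, params$artifact_rate)
    for (b in seq_len(n_new)) {
      area <- runif(1, area_range[1], area_range[2])
      rad <- sqrt(area / pi)
      r0 <- runif(1, rad + 5, shp[1] - rad - 5)
      c0 <- runif(1, rad + 5, shp[2] - rad - 5)
      depth <- runif(1, 50, 90)
      rr <- max(1, floor(r0 - 3 * rad)):min(shp[1], ceiling(r0 + 3 * rad))
      cc <- max(1, floor(c0 - 3 * rad)):min(shp[2], ceiling(c0 + 3 * rad))
      d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      bump <- depth * exp(-d2 / (2 * (rad / 1.3)^2))
      layer[rr, cc] <- pmax(layer[rr, cc], bump)
      blobs[[length(blobs) + 1]] <- tibble(frame = k, row = r0, col = c0,
                                           radius = rad, depth = depth)
    }
    if (length(blobs))
      stack$frames[[k]] <- clamp(round(stack$frames[[k]] - layer), 0, 255)
  }
  attr(stack, "blobs") <- if (length(blobs)) dplyr::bind_rows(blobs) else
    tibble(frame = integer(), row = numeric(), col = numeric(),
           radius = numeric(), depth = numeric())
  stack
}

#' Simulate a full plate: architecture, rasterization and artifacts
#'
#' Convenience wrapper chaining [simulate_architecture()],
#' [rasterize_timeseries()] and [inject_artifacts()].
#'
#' @param params a [sim_params()].
#' @return an [image_timeseries()] carrying the ground-truth attributes of
#'   [rasterize_timeseries()] and the blob ledger of [inject_artifacts()].
#' @export
simulate_plate <- function(params) {
  model <- simulate_architecture(params)
  stack <- rasterize_timeseries(model, params)
  inject_artifacts(stack, params)
}

#' Write a simulated plate to disk
#'
#' Emits numbered TIFF frames, the ground-truth RSML and a JSON manifest of
#' parameters and applied jitter transforms.
#'
#' @param stack result of [simulate_plate()].
#' @param dir output directory.
#' @param id plate identifier used in file names.
#' @return `dir`, invisibly.
#' @export
write_simulated_plate <- function(stack, dir, id = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries(stack, dir, prefix = sprintf("plate_%d", id))
  write_rsml(attr(stack, "model"),
             file.path(dir, sprintf("plate_%d_truth.rsml", id)))
  jit <- attr(stack, "jitter")
  manifest <- list(
    plate = id,
    timestep_h = stack$timestep_h,
    px_size_um = stack$px_size_um,
    jitter = lapply(jit, function(j)
      list(theta = j$theta, dx = j$dx, dy = j$dy, center = j$center)))
  jsonlite::write_json(manifest,
                       file.path(dir, sprintf("plate_%d_manifest.json", id)),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
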