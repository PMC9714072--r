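#' Simulation parameters
#'
#' The defaults state the acquisition regime of the reference platform: 5
#' plants per 120 mm plate observed 21 times at 8 h intervals, 19 um/px,
#' ~100 gray levels of contrast between root centerline and background.
#' Growth rates reproduce a typical Arabidopsis control population (80 mm
#' primaries and ~15-25 laterals of 5-25 mm after 160 h). `px_size_um` can
#' be raised to rasterize a geometrically identical world at a coarser,
#' cheaper resolution.
#'
#' @param n_plants seedlings per plate.
#' @param n_timesteps number of observations `N_t` (>= 2).
#' @param timestep_h hours between observations.
#' @param px_size_um pixel size in micrometres.
#' @param image_shape `c(rows, cols)`; default covers a 120 mm square plate
#'   at the configured pixel size.
#' @param primary_rate,lateral_rate `c(mean, sd)` elongation rates, mm/h.
#' @param lateral_density lateral emergences per mm of primary root.
#' @param tortuosity heading noise, radians sd per growth sub-step.
#' @param crossing_bias probability that a lateral is steered sideways so
#'   that its trajectory crosses a neighbouring plant's organs.
#' @param background_level background gray level (8-bit scale).
#' @param root_contrast gray-level drop at the root centerline.
#' @param noise_sd per-pixel Gaussian sensor noise, gray levels.
#' @param jitter `c(max_translation_px, max_rotation_deg)` rigid plate
#'   jitter per frame.
#' @param artifact_rate expected condensation/dirt blobs per frame.
#' @param root_width_px full width of the rasterized root tube.
#' @param emergence_delay_h mean delay between the primary tip passing an
#'   insertion point and the lateral emerging there.
#' @param lateral_stop_prob probability that a lateral stops growing before
#'   the end of the observation window.
#' @param plate_mm physical plate width, mm.
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given `seed`.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_plants = 5, n_timesteps = 21, timestep_h = 8,
                       px_size_um = 19, image_shape = NULL,
                       primary_rate = c(0.5, 0.05),
                       lateral_rate = c(0.15, 0.04),
                       lateral_density = 0.25, tortuosity = 0.06,
                       crossing_bias = 0.25, background_level = 180,
                       root_contrast = 100, noise_sd = 3,
                       jitter = c(10, 0.5), artifact_rate = 0.5,
                       root_width_px = 3, emergence_delay_h = 40,
                       lateral_stop_prob = 0.05, plate_mm = 120,
                       seed = 1) {
  stopifnot(n_timesteps >= 2, all(primary_rate >= 0),
            all(lateral_rate >= 0), root_contrast > 0, n_plants >= 1)
  px_mm <- px_size_um / 1000
  image_shape <- image_shape %||% rep(round(plate_mm / px_mm), 2)
  p <- structure(as.list(environment()), class = "sim_params")
  # sizing check: the deepest plausible primary must fit the image
  depth_mm <- p$seed_depth_mm <- 8
  total_h <- (n_timesteps - 1) * timestep_h
  need_mm <- depth_mm + (primary_rate[1] + 2 * primary_rate[2]) * total_h + 2
  if (need_mm > image_shape[1] * px_mm)
    stop(sprintf(paste0("image too small: primaries can reach %.0f mm but ",
                        "the image holds %.0f mm at %g um/px"),
                 need_mm, image_shape[1] * px_mm, px_size_um))
  p
}

rtrunc_norm <- function(n, mean, sd, lo) pmax(rnorm(n, mean, sd), lo)

mm_to_px <- function(mm, px_size_um) mm * 1000 / px_size_um + 1

grow_organ <- function(x0, y0, t0_h, rate, heading0, relax, pull,
                       tortuosity, total_h, dt_h, bounds_mm,
                       stop_h = Inf) {
  # directed random walk in mm; heading is the angle from straight down
  # (positive = +x). Returns matrix (x_mm, y_mm, t_h).
  n_max <- ceiling((total_h - t0_h) / dt_h)
  if (n_max < 1) return(cbind(x0, y0, t0_h))
  xs <- numeric(n_max + 1); ys <- numeric(n_max + 1); ts <- numeric(n_max + 1)
  xs[1] <- x0; ys[1] <- y0; ts[1] <- t0_h
  phi <- heading0
  k <- 1
  while (ts[k] < total_h - 1e-9 && ts[k] < stop_h) {
    step_h <- min(dt_h, total_h - ts[k], stop_h - ts[k])
    step <- rate * step_h
    phi <- phi * relax - pull * sign(phi) + rnorm(1, 0, tortuosity)
    x <- xs[k] + step * sin(phi)
    y <- ys[k] + step * cos(phi)
    if (y > bounds_mm[1] || x < 1 || x > bounds_mm[2]) break
    k <- k + 1
    xs[k] <- x; ys[k] <- y; ts[k] <- ts[k - 1] + step_h
  }
  cbind(x = xs[1:k], y = ys[1:k], t = ts[1:k])
}

#' Simulate a ground-truth root system architecture
#'
#' Generates one plate of seedlings as timed polylines: one primary per
#' plant growing predominantly downward with heading noise, and laterals
#' emerging at Poisson-distributed positions along the primary (outside a
#' refractory zone behind the tip), growing sideways then bending down.
#' With `crossing_bias > 0`, part of the laterals are steered toward the
#' neighbouring plant so their trajectories cross other organs with a
#' temporal offset. Radicles have zero length at the first observation, so
#' every covered pixel appears strictly after the first frame.
#'
#' @param params a [sim_params()].
#' @return a [root_system_model()] in pixel coordinates, with per-plant
#'   seed positions in `attr(, "seeds_px")`.
#' @export
simulate_architecture <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 1))
  px_mm <- params$px_size_um / 1000
  shape_mm <- params$image_shape * px_mm
  total_h <- (params$n_timesteps - 1) * params$timestep_h
  dt_h <- params$timestep_h / 4
  seed_y <- params$seed_depth_mm
  seed_x <- (seq_len(params$n_plants) - 0.5) *
    shape_mm[2] / params$n_plants
  bounds <- c(shape_mm[1] - 1, shape_mm[2] - 1)
  h_to_obs <- function(h) 1 + h / params$timestep_h
  plants <- vector("list", params$n_plants)
  for (i in seq_len(params$n_plants)) {
    r_p <- rtrunc_norm(1, params$primary_rate[1], params$primary_rate[2],
                       0.05)
    pm <- grow_organ(seed_x[i], seed_y, 0, r_p, rnorm(1, 0, 0.05),
                     relax = 0.85, pull = 0.002,
                     tortuosity = params$tortuosity, total_h = total_h,
                     dt_h = dt_h, bounds_mm = bounds)
    primary <- root_organ(mm_to_px(pm[, 1], params$px_size_um),
                          mm_to_px(pm[, 2], params$px_size_um),
                          h_to_obs(pm[, 3]), order = 1, id = "p")
    cum <- c(0, cumsum(sqrt(rowSums(diff(pm[, 1:2, drop = FALSE])^2))))
    laterals <- list()
    if (params$lateral_density > 0 && nrow(pm) > 2) {
      final_len <- max(cum)
      refractory <- 8
      usable <- max(0, final_len - refractory)
      n_lat <- rpois(1, params$lateral_density * usable)
      if (n_lat > 0) {
        s_pos <- sort(runif(n_lat, 0.5, usable))
        for (j in seq_len(n_lat)) {
          at <- approx(cum, seq_len(nrow(pm)), xout = s_pos[j])$y
          i0 <- floor(at); frac <- at - i0
          ins <- (1 - frac) * pm[i0, ] + frac * pm[min(i0 + 1, nrow(pm)), ]
          t_pass <- ins[3]
          t_emerge <- t_pass + rtrunc_norm(1, params$emergence_delay_h, 8, 12)
          if (t_emerge > total_h - params$timestep_h) next
          side <- sample(c(-1, 1), 1)
          seeker <- runif(1) < params$crossing_bias
          if (seeker) {
            # steer toward the neighbouring plant (or inward at the
            # borders), with spread headings so that crossings are
            # transversal (hidden parallel runs are infrequent)
            if (i == 1) side <- 1
            else if (i == params$n_plants) side <- -1
            heading0 <- side * runif(1, 60, 88) * pi / 180
            relax <- 0.997; pull <- 0.0015
          } else {
            heading0 <- side * (65 + rnorm(1, 0, 10)) * pi / 180
            relax <- 0.985; pull <- 0.004
          }
          r_l <- rtrunc_norm(1, params$lateral_rate[1],
                             params$lateral_rate[2], 0.02)
          stop_h <- Inf
          if (runif(1) < params$lateral_stop_prob)
            stop_h <- t_emerge + runif(1, 0.5, 6) * params$timestep_h
          lm <- grow_organ(ins[1], ins[2], t_emerge, r_l, heading0,
                           relax = relax, pull = pull,
                           tortuosity = params$tortuosity,
                           total_h = total_h, dt_h = dt_h,
                           bounds_mm = bounds, stop_h = stop_h)
          if (nrow(lm) < 2) next
          laterals[[length(laterals) + 1]] <- root_organ(
            mm_to_px(lm[, 1], params$px_size_um),
            mm_to_px(lm[, 2], params$px_size_um),
            h_to_obs(lm[, 3]), order = 2,
            id = paste0("l", length(laterals) + 1))
        }
      }
    }
    plants[[i]] <- list(primary = primary, laterals = laterals)
  }
  out <- root_system_model(plants, params$px_size_um, params$timestep_h,
                           params$n_timesteps,
                           seed_row = mm_to_px(seed_y, params$px_size_um))
  attr(out, "seeds_px") <- cbind(x = mm_to_px(seed_x, params$px_size_um),
                                 y = rep(mm_to_px(seed_y, params$px_size_um),
                                         params$n_plants))
  attr(out, "params") <- params
  out
}
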