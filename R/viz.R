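model_apparition_map <- function(model, S) {
  # per-pixel apparition time of the segmented architecture: each root
  # pixel takes the (interpolated) time of the nearest centerline pixel
  shape <- dim(S)
  seeds <- NULL; vals <- NULL
  for (e in model_organs(model)) {
    o <- e$organ
    if (length(o$x) < 2) next
    cl <- polyline_cumlen(cbind(o$x, o$y))
    n_s <- max(2, ceiling(max(cl)))
    s <- seq(0, max(cl), length.out = n_s)
    xs <- approx(cl, o$x, xout = s, ties = "ordered")$y
    ys <- approx(cl, o$y, xout = s, ties = "ordered")$y
    ts <- approx(cl, o$t, xout = s, ties = "ordered")$y
    rr <- clamp(round(ys), 1, shape[1])
    cc <- clamp(round(xs), 1, shape[2])
    seeds <- rbind(seeds, cbind(rr, cc))
    vals <- c(vals, ts)
  }
  if (is.null(seeds)) return(matrix(Inf, shape[1], shape[2]))
  mask <- matrix(as.integer(S > 0), shape[1], shape[2])
  mask[seeds] <- 1L
  geo <- geodesic_cpp(mask, seeds, vals)
  app <- geo$val
  app[mask == 0L] <- Inf
  app[!is.finite(app)] <- Inf
  app
}

rate_color <- function(rate, max_rate) {
  # blue (slow) -> yellow -> red (fast)
  f <- clamp(rate / max(max_rate, 1e-9), 0, 1)
  cbind(r = 60 + 195 * f, g = 80 + 160 * (1 - abs(2 * f - 1)),
        b = 220 * (1 - f))
}

write_ppm <- function(rgb_list, path) {
  nr <- nrow(rgb_list$r); nc <- ncol(rgb_list$r)
  px <- array(0L, c(3, nc, nr))
  px[1, , ] <- t(as.integer(round(clamp(rgb_list$r, 0, 255))))
  px[2, , ] <- t(as.integer(round(clamp(rgb_list$g, 0, 255))))
  px[3, , ] <- t(as.integer(round(clamp(rgb_list$b, 0, 255))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", nc, nr), con, eos = NULL)
  writeBin(as.raw(as.vector(px)), con)
  invisible(path)
}

#' Render the interpolated time-lapse of the growing root system
#'
#' Builds one frame every `step_minutes` from a time series observed every
#' `timestep_h` hours. Each pixel of the segmented architecture carries the
#' apparition time of the nearest centerline pixel; at an interpolated
#' time `t` between keyframes `i` and `i+1`, the growing mask
#' (apparition <= t) is filled from frame `i+1` and its complement from
#' frame `i`. Near each keyframe the composite is crossfaded linearly with
#' the next keyframe pair, and root tips are overlaid as colored markers
#' encoding the current elongation rate.
#'
#' @param model a [root_system_model()].
#' @param stack the registered [image_timeseries()].
#' @param S the filtered [apparition_image()].
#' @param step_minutes interpolation step (default 15 min).
#' @param fade_minutes half-width of the crossfade window around each
#'   keyframe.
#' @param out_dir if set, frames are written as numbered PPM files and
#'   only their paths are returned.
#' @param tip_radius_px radius of the tip markers.
#' @return invisibly, the list of frames (RGB component lists) or written
#'   paths; `attr(, "times")` holds the interpolated times.
#' @export
render_timelapse <- function(model, stack, S, step_minutes = 15,
                             fade_minutes = 30, out_dir = NULL,
                             tip_radius_px = 3) {
  n_t <- length(stack$frames)
  stopifnot(model$n_timesteps == n_t)
  step_obs <- step_minutes / (stack$timestep_h * 60)
  times <- seq(1, n_t, by = step_obs)
  app <- model_apparition_map(model, S)
  organs <- model_organs(model)
  px_mm <- stack$px_size_um / 1000
  # per-organ tip position and rate at arbitrary t
  tip_at <- function(o, t) {
    if (t < o$t[1]) return(NULL)
    i <- findInterval(t, o$t)
    i <- clamp(i, 1, length(o$t))
    xy <- c(o$x[i], o$y[i])
    # elongation rate around t, mm/h
    lo <- max(t - 0.5, o$t[1]); hi <- min(t + 0.5, o$t[length(o$t)])
    cl <- polyline_cumlen(cbind(o$x, o$y))
    len_at <- function(tt) approx(o$t, cl, xout = tt, rule = 2,
                                  ties = "max")$y
    rate <- if (hi > lo)
      (len_at(hi) - len_at(lo)) * px_mm / ((hi - lo) * stack$timestep_h)
      else 0
    list(xy = xy, rate = rate)
  }
  fade_obs <- fade_minutes / (stack$timestep_h * 60)
  composite_at <- function(t) {
    i <- clamp(floor(t), 1, n_t - 1)
    m <- app <= t
    base <- stack$frames[[i]]
    nxt <- stack$frames[[i + 1]]
    comp <- base
    comp[m] <- nxt[m]
    comp
  }
  out <- vector("list", length(times))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  max_rate <- 0.6   # mm/h, colormap ceiling
  for (k in seq_along(times)) {
    t <- times[k]
    comp <- composite_at(t)
    # crossfade near the next keyframe
    t_next <- min(floor(t) + 1, n_t)
    dist_key <- t_next - t
    if (dist_key < fade_obs && t_next < n_t) {
      wfade <- (1 - dist_key / fade_obs) / 2
      comp2 <- composite_at(t_next + 1e-6)
      comp <- (1 - wfade) * comp + wfade * comp2
    }
    rgb <- list(r = comp, g = comp, b = comp)
    for (e in organs) {
      tp <- tip_at(e$organ, t)
      if (is.null(tp)) next
      col <- rate_color(tp$rate, max_rate)
      rr <- round(tp$xy[2]) + (-tip_radius_px:tip_radius_px)
      cc <- round(tp$xy[1]) + (-tip_radius_px:tip_radius_px)
      rr <- rr[rr >= 1 & rr <= nrow(comp)]
      cc <- cc[cc >= 1 & cc <= ncol(comp)]
      rgb$r[rr, cc] <- col[1]; rgb$g[rr, cc] <- col[2]
      rgb$b[rr, cc] <- col[3]
    }
    if (!is.null(out_dir)) {
      p <- file.path(out_dir, sprintf("frame_%05d.ppm", k))
      write_ppm(rgb, p)
      out[[k]] <- p
    } else {
      out[[k]] <- rgb
    }
  }
  attr(out, "times") <- times
  invisible(out)
}
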