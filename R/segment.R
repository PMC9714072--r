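#' Apparition-time label image
#'
#' Integer image `S`: `S(p) = 0` for background, otherwise the observation
#' index at which a root first covers pixel `p`. The masks
#' `M_t = {p : 0 < S(p) <= t}` are nested in `t` by construction.
#'
#' @param labels integer matrix of labels in `0..n_timesteps`.
#' @param n_timesteps number of observations.
#' @param px_size_um,timestep_h acquisition geometry.
#' @return an `apparition_image`.
#' @export
apparition_image <- function(labels, n_timesteps, px_size_um = 19,
                             timestep_h = 8) {
  stopifnot(is.matrix(labels))
  structure(labels, n_timesteps = as.integer(n_timesteps),
            px_size_um = px_size_um, timestep_h = timestep_h,
            class = c("apparition_image", "matrix", "array"))
}

#' @export
print.apparition_image <- function(x, ...) {
  cat(sprintf("<apparition_image> %d x %d px, N_t = %d, %d root px\n",
              nrow(x), ncol(x), attr(x, "n_timesteps"), sum(x > 0)))
  invisible(x)
}

#' Apparition time of a single pixel intensity series
#'
#' Two-threshold temporal change-point detector. The maximum mean shift
#' `mean(series[1..k]) - mean(series[(k+1)..N_t])` over all split points
#' must reach `s1` (the pixel darkens durably), and the maximum successive
#' drop `series[k] - series[k+1]` must reach `s2`; the label is then the
#' observation index following the maximal drop (earliest index on ties).
#' Either test failing classifies the pixel as background (label 0).
#'
#' @param series numeric intensity sequence (one value per observation).
#' @param s1 mean-shift threshold, gray levels (8-bit scale).
#' @param s2 successive-drop threshold, gray levels.
#' @return integer label in `0..N_t`.
#' @export
pixel_apparition_time <- function(series, s1 = 25, s2 = 10) {
  n <- length(series)
  if (n < 2) stop("series must have >= 2 observations")
  cum <- cumsum(series)
  k <- seq_len(n - 1)
  shift <- cum[k] / k - (cum[n] - cum[k]) / (n - k)
  if (max(shift) < s1) return(0L)
  drops <- series[-n] - series[-1]
  if (max(drops) < s2) return(0L)
  as.integer(which.max(drops) + 1L)
}

#' Segment a registered stack into an apparition-time label image
#'
#' Applies the per-pixel change-point detector of
#' [pixel_apparition_time()] independently to every pixel of the stack.
#'
#' @param stack a registered [image_timeseries()] (a warning is emitted if
#'   no transforms are recorded).
#' @param s1,s2 detector thresholds in 8-bit gray levels.
#' @return an unfiltered [apparition_image()].
#' @export
segment_stack <- function(stack, s1 = 25, s2 = 10) {
  if (is.null(stack$transforms))
    warning("stack carries no registration transforms; segmenting as-is")
  n_t <- length(stack$frames)
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  # running cumulative sum for the mean-shift test
  cum <- matrix(0, nr, nc)
  cums <- vector("list", n_t)
  for (k in seq_len(n_t)) {
    cum <- cum + stack$frames[[k]]
    cums[[k]] <- cum
  }
  tot <- cums[[n_t]]
  max_shift <- matrix(-Inf, nr, nc)
  for (k in seq_len(n_t - 1)) {
    shift <- cums[[k]] / k - (tot - cums[[k]]) / (n_t - k)
    max_shift <- pmax(max_shift, shift)
  }
  max_drop <- matrix(-Inf, nr, nc)
  argmax_drop <- matrix(0L, nr, nc)
  for (k in seq_len(n_t - 1)) {
    d <- stack$frames[[k]] - stack$frames[[k + 1]]
    better <- d > max_drop                      # strict: earliest tie wins
    max_drop[better] <- d[better]
    argmax_drop[better] <- k
  }
  lab <- argmax_drop + 1L
  lab[max_shift < s1 | max_drop < s2] <- 0L
  apparition_image(lab, n_t, stack$px_size_um, stack$timestep_h)
}

#' Remove small connected components from a label image
#'
#' Computes the 4-connected components of the nonzero mask and resets to
#' background every pixel belonging to a component smaller than
#' `min_component_px`. At the reference resolution of 19 um/px the default
#' 2000 px corresponds to rejecting candidate root systems whose cumulative
#' organ length at the last observation is below 38 mm (for a 1-px-wide
#' curve).
#'
#' @param S an [apparition_image()].
#' @param min_component_px minimum component size in pixels.
#' @return the filtered [apparition_image()].
#' @export
filter_components <- function(S, min_component_px = 2000) {
  mask <- matrix(as.integer(S > 0), nrow(S), ncol(S))
  if (!any(mask > 0)) return(S)
  lab <- cc_label_cpp(mask, 4L)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_component_px)
  if (length(small)) {
    out <- unclass(S)
    out[matrix(lab %in% small, nrow(S), ncol(S))] <- 0L
    S <- apparition_image(out, attr(S, "n_timesteps"),
                          attr(S, "px_size_um"), attr(S, "timestep_h"))
  }
  S
}

#' Physical length equivalent of a component-size threshold
#'
#' For a 1-px-wide curve, a component of `min_component_px` pixels has a
#' cumulative length of `min_component_px * px_size_um` micrometres; this
#' helper returns it in millimetres (e.g. 2000 px at 19 um/px = 38 mm).
#'
#' @param min_component_px component-size threshold, pixels.
#' @param px_size_um pixel size, micrometres.
#' @return length in mm.
#' @export
component_threshold_mm <- function(min_component_px = 2000,
                                   px_size_um = 19) {
  min_component_px * px_size_um / 1000
}
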