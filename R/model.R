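#' Root organ: a timed polyline
#'
#' Nodes are ordered along the organ from base to tip; coordinates are in
#' pixels (x = column, y = row, origin top-left, y increasing downward) and
#' `t` is the continuous 1-based observation index at which the tip reached
#' the node.
#'
#' @param x,y,t numeric node vectors.
#' @param order 1 (primary) or 2 (lateral).
#' @param extrapolated logical per node; `TRUE` for nodes added by the
#'   extrapolation post-processes rather than observed.
#' @param id organ identifier within its plant.
#' @return a `root_organ`.
#' @export
root_organ <- function(x, y, t, order = 1, extrapolated = NULL, id = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(t) == n, n >= 1)
  extrapolated <- extrapolated %||% rep(FALSE, n)
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 extrapolated = extrapolated, order = as.integer(order),
                 id = id),
            class = "root_organ")
}

organ_xy <- function(organ) cbind(organ$x, organ$y)

#' Root system model: per-plant forest of timed organs
#'
#' @param plants list of plants; each plant is a list with `primary` (a
#'   [root_organ()]) and `laterals` (list of [root_organ()]s).
#' @param px_size_um pixel size, micrometres.
#' @param timestep_h hours between observations.
#' @param n_timesteps number of observations `N_t`.
#' @param seed_row image row of the seed line (used as depth origin).
#' @return a `root_system_model`.
#' @export
root_system_model <- function(plants, px_size_um, timestep_h, n_timesteps,
                              seed_row = 1) {
  structure(list(plants = plants, px_size_um = px_size_um,
                 timestep_h = timestep_h, n_timesteps = n_timesteps,
                 seed_row = seed_row),
            class = "root_system_model")
}

#' @export
print.root_system_model <- function(x, ...) {
  nl <- vapply(x$plants, function(p) length(p$laterals), integer(1))
  cat(sprintf(
    "<root_system_model> %d plants, %d laterals, N_t = %d (%g h, %g um/px)\n",
    length(x$plants), sum(nl), x$n_timesteps, x$timestep_h, x$px_size_um))
  invisible(x)
}

#' Iterate over all organs of a model
#' @param model a [root_system_model()].
#' @return list of entries `list(plant, organ_index, organ)`; primaries come
#'   first in each plant, then laterals in stored order.
#' @export
model_organs <- function(model) {
  out <- list()
  for (pi in seq_along(model$plants)) {
    p <- model$plants[[pi]]
    out[[length(out) + 1]] <- list(plant = pi, organ = p$primary,
                                   organ_id = p$primary$id %||% "p")
    for (li in seq_along(p$laterals))
      out[[length(out) + 1]] <- list(plant = pi, organ = p$laterals[[li]],
                                     organ_id = p$laterals[[li]]$id %||%
                                       paste0("l", li))
  }
  out
}

#' Ground-truth crossing events of a model
#'
#' Enumerates points where two distinct organs intersect in the image
#' plane with a temporal offset of at least `min_offset` observation
#' intervals (the later organ grew over the earlier one) and a true "X"
#' pattern: both organs must extend at least `min_overhang_px` beyond the
#' intersection on both sides. Encounters where one organ merely ends on
#' the other are not crossings. Near-tangential contacts producing
#' several intersection points within `dedup_px` collapse to one event.
#'
#' @param model a [root_system_model()].
#' @param min_offset minimum |t difference| in observation units.
#' @param min_overhang_px minimum arc length of each organ on both sides
#'   of the intersection.
#' @param dedup_px collapse radius for near-duplicate intersection points
#'   of the same organ pair.
#' @return tibble with the crossing position, the passage times of both
#'   organs and their identities.
#' @export
find_crossings <- function(model, min_offset = 1, min_overhang_px = 12,
                           dedup_px = 15) {
  organs <- model_organs(model)
  segs <- lapply(organs, function(e) {
    o <- e$organ
    n <- length(o$x)
    if (n < 2) return(NULL)
    cl <- polyline_cumlen(cbind(o$x, o$y))
    tibble(x0 = o$x[-n], y0 = o$y[-n], t0 = o$t[-n],
           x1 = o$x[-1], y1 = o$y[-1], t1 = o$t[-1],
           s0 = cl[-n], s1 = cl[-1])
  })
  total_len <- vapply(segs, function(s)
    if (is.null(s)) 0 else max(s$s1), numeric(1))
  rows <- list()
  for (i in seq_along(organs)) {
    for (j in seq_along(organs)) {
      if (j <= i) next
      a <- segs[[i]]; b <- segs[[j]]
      if (is.null(a) || is.null(b)) next
      # bounding-box prefilter on whole organs
      if (max(a$x0, a$x1) < min(b$x0, b$x1) - 1 ||
          max(b$x0, b$x1) < min(a$x0, a$x1) - 1 ||
          max(a$y0, a$y1) < min(b$y0, b$y1) - 1 ||
          max(b$y0, b$y1) < min(a$y0, a$y1) - 1) next
      hit <- segment_intersections(a, b)
      if (is.null(hit) || nrow(hit) == 0) next
      for (k in seq_len(nrow(hit))) {
        dt <- abs(hit$ta[k] - hit$tb[k])
        if (dt < min_offset) next
        # X pattern: both organs continue beyond the intersection (this
        # also excludes the attachment point of a lateral on its parent)
        if (hit$sa[k] < min_overhang_px ||
            hit$sa[k] > total_len[i] - min_overhang_px) next
        if (hit$sb[k] < min_overhang_px ||
            hit$sb[k] > total_len[j] - min_overhang_px) next
        # the tracking framework assumes the later root traverses the
        # area at least one timestep after the earlier one; require the
        # offset over the whole contact zone, not just at the crossing
        # point (tangential contacts are simultaneous-occupancy events,
        # not crossings)
        late_ij <- if (hit$ta[k] > hit$tb[k]) i else j
        early_ij <- if (late_ij == i) j else i
        if (!zone_offset_ok(organs[[late_ij]]$organ,
                            organs[[early_ij]]$organ,
                            if (late_ij == i) hit$sa[k] else hit$sb[k],
                            min_offset, min_overhang_px)) next
        rows[[length(rows) + 1]] <- tibble(
          x = hit$x[k], y = hit$y[k],
          organ_a = i, organ_b = j,
          plant_a = organs[[i]]$plant, plant_b = organs[[j]]$plant,
          t_early = min(hit$ta[k], hit$tb[k]),
          t_late = max(hit$ta[k], hit$tb[k]),
          late_organ = if (hit$ta[k] > hit$tb[k]) i else j)
      }
    }
  }
  if (!length(rows)) return(tibble(
    x = numeric(), y = numeric(), organ_a = integer(), organ_b = integer(),
    plant_a = integer(), plant_b = integer(), t_early = numeric(),
    t_late = numeric(), late_organ = integer()))
  out <- dplyr::bind_rows(rows)
  # collapse near-duplicate hits of the same organ pair (tangential
  # contacts yield several intersection points in one crossing zone)
  out <- out[order(out$organ_a, out$organ_b, out$t_late), ]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (k in 2:nrow(out)) {
      prev <- which(keep[1:(k - 1)])
      prev <- prev[out$organ_a[prev] == out$organ_a[k] &
                   out$organ_b[prev] == out$organ_b[k]]
      if (length(prev) &&
          any((out$x[prev] - out$x[k])^2 +
              (out$y[prev] - out$y[k])^2 < dedup_px^2)) keep[k] <- FALSE
    }
  }
  out[keep, ]
}

zone_offset_ok <- function(late, early, s_cross, min_offset, zone_px) {
  # minimum temporal offset between the late organ's passage and the
  # early organ's presence over the whole contact zone around the
  # crossing point
  cl_l <- polyline_cumlen(cbind(late$x, late$y))
  cl_e <- polyline_cumlen(cbind(early$x, early$y))
  s <- seq(max(0, s_cross - zone_px), min(max(cl_l), s_cross + zone_px),
           length.out = 9)
  lx <- approx(cl_l, late$x, xout = s)$y
  ly <- approx(cl_l, late$y, xout = s)$y
  lt <- approx(cl_l, late$t, xout = s)$y
  se <- seq(0, max(cl_e), by = 2)
  ex <- approx(cl_e, early$x, xout = se)$y
  ey <- approx(cl_e, early$y, xout = se)$y
  et <- approx(cl_e, early$t, xout = se)$y
  for (q in seq_along(s)) {
    d2 <- (ex - lx[q])^2 + (ey - ly[q])^2
    jn <- which.min(d2)
    if (sqrt(d2[jn]) <= 4 && lt[q] - et[jn] < min_offset) return(FALSE)
  }
  TRUE
}

segment_intersections <- function(a, b) {
  # all intersection points between segment sets a and b (vectorized over b
  # for each segment of a), with arc positions along both organs
  res <- list()
  for (k in seq_len(nrow(a))) {
    p <- c(a$x0[k], a$y0[k]); r <- c(a$x1[k] - a$x0[k], a$y1[k] - a$y0[k])
    qx <- b$x0; qy <- b$y0; sx <- b$x1 - b$x0; sy <- b$y1 - b$y0
    denom <- r[1] * sy - r[2] * sx
    ok <- abs(denom) > 1e-12
    if (!any(ok)) next
    tpar <- ((qx - p[1]) * sy - (qy - p[2]) * sx) / denom
    upar <- ((qx - p[1]) * r[2] - (qy - p[2]) * r[1]) / denom
    hit <- ok & tpar >= 0 & tpar <= 1 & upar >= 0 & upar <= 1
    if (!any(hit)) next
    res[[length(res) + 1]] <- tibble(
      x = p[1] + tpar[hit] * r[1], y = p[2] + tpar[hit] * r[2],
      ta = a$t0[k] + tpar[hit] * (a$t1[k] - a$t0[k]),
      tb = b$t0[hit] + upar[hit] * (b$t1[hit] - b$t0[hit]),
      sa = a$s0[k] + tpar[hit] * (a$s1[k] - a$s0[k]),
      sb = b$s0[hit] + upar[hit] * (b$s1[hit] - b$s0[hit]))
  }
  if (!length(res)) return(NULL)
  dplyr::bind_rows(res)
}
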