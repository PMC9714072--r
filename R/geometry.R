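#' Geometry configuration
#'
#' @param dp_tol_px Douglas-Peucker decimation tolerance, px.
#' @param seed_target_row image row of the seed line for upstream primary
#'   extrapolation; `NULL` disables it.
#' @param min_growth_timepoints isolated roots stopping early are kept only
#'   if they grew over at least this many time points.
#' @param include_extrapolated whether extrapolated segments count toward
#'   length phenes (forwarded to downstream measurements).
#' @param attach_snap_px lateral base nodes within this distance of the
#'   parent centerline are snapped onto it (insertion convention).
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(dp_tol_px = 1.5, seed_target_row = NULL,
                            min_growth_timepoints = 3,
                            include_extrapolated = FALSE,
                            attach_snap_px = 6) {
  structure(as.list(environment()), class = "geometry_config")
}

project_point_polyline <- function(pt, xy) {
  # nearest point on a polyline to pt; returns the point and the distance
  if (nrow(xy) == 1)
    return(list(point = xy[1, ], dist = sqrt(sum((xy[1, ] - pt)^2))))
  a <- xy[-nrow(xy), , drop = FALSE]
  b <- xy[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  tt <- ((pt[1] - a[, 1]) * ab[, 1] + (pt[2] - a[, 2]) * ab[, 2]) /
    pmax(len2, 1e-12)
  tt <- clamp(tt, 0, 1)
  px <- a[, 1] + tt * ab[, 1]
  py <- a[, 2] + tt * ab[, 2]
  d2 <- (px - pt[1])^2 + (py - pt[2])^2
  j <- which.min(d2)
  list(point = c(px[j], py[j]), dist = sqrt(d2[j]))
}

pix_rc <- function(pixels, nr) {
  cbind(row = ((pixels - 1) %% nr) + 1, col = ((pixels - 1) %/% nr) + 1)
}

crop_mask <- function(pixels, shape, margin = 1) {
  # binary mask of the component restricted to its bounding box (plus a
  # margin), with the offset needed to map local coords back to the image
  nr <- shape[1]
  rc <- pix_rc(pixels, nr)
  r0 <- max(1, min(rc[, "row"]) - margin)
  c0 <- max(1, min(rc[, "col"]) - margin)
  r1 <- min(shape[1], max(rc[, "row"]) + margin)
  c1 <- min(shape[2], max(rc[, "col"]) + margin)
  mask <- matrix(0L, r1 - r0 + 1, c1 - c0 + 1)
  mask[cbind(rc[, "row"] - r0 + 1, rc[, "col"] - c0 + 1)] <- 1L
  list(mask = mask, r0 = r0, c0 = c0, rc = rc)
}

#' Frontier point between two adjacent components
#'
#' Enumerates the shared pixel edges of two 4-adjacent pixel sets, orders
#' them along the frontier chain, and returns the midpoint of the median
#' element (the lower-index median for even-length frontiers).
#'
#' @param pix1,pix2 linear pixel indices of the two components.
#' @param nr number of image rows.
#' @return `c(x, y)` of the central-most frontier element.
#' @export
locate_frontier_point <- function(pix1, pix2, nr) {
  set2 <- unique(pix2)
  # 4-neighbour offsets in linear (column-major) indexing
  offs <- c(-1L, 1L, -nr, nr)
  pts <- NULL
  rc1 <- pix_rc(pix1, nr)
  for (k in seq_along(offs)) {
    nb <- pix1 + offs[k]
    # guard row wrap-around for the vertical offsets
    ok <- switch(k, rc1[, "row"] > 1, rc1[, "row"] < nr, TRUE, TRUE)
    hit <- ok & (nb %in% set2)
    if (any(hit)) {
      rc2 <- pix_rc(nb[hit], nr)
      mid <- cbind(x = (rc1[hit, "col"] + rc2[, "col"]) / 2,
                   y = (rc1[hit, "row"] + rc2[, "row"]) / 2)
      pts <- rbind(pts, mid)
    }
  }
  if (is.null(pts)) stop("components are not 4-adjacent")
  pts <- unique(pts)
  if (nrow(pts) == 1) return(c(x = pts[1, 1], y = pts[1, 2]))
  # order along the frontier chain by projection on its principal axis,
  # oriented deterministically (ascending (y, x) from first to last)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  sv <- svd(d)
  proj <- d %*% sv$v[, 1]
  ord <- order(proj, pts[, 2], pts[, 1])
  first <- pts[ord[1], ]; last <- pts[ord[length(ord)], ]
  if (first[2] > last[2] || (first[2] == last[2] && first[1] > last[1]))
    ord <- rev(ord)
  med <- pts[ord[ceiling(nrow(pts) / 2)], ]
  c(x = unname(med[1]), y = unname(med[2]))
}

frontier_or_gap <- function(pix1, pix2, nr) {
  # frontier point for adjacent components; for reconnected (spliced)
  # chain links separated by a crossing region, the midpoint of the
  # closest pixel pair bridges the gap instead
  rc1 <- pix_rc(pix1, nr); rc2 <- pix_rc(pix2, nr)
  b1 <- range(rc1[, "row"]); b2 <- range(rc2[, "row"])
  c1 <- range(rc1[, "col"]); c2 <- range(rc2[, "col"])
  maybe_adjacent <- b1[1] <= b2[2] + 1 && b2[1] <= b1[2] + 1 &&
    c1[1] <= c2[2] + 1 && c2[1] <= c1[2] + 1
  if (maybe_adjacent) {
    out <- tryCatch(locate_frontier_point(pix1, pix2, nr),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  # closest pair midpoint (sub-sample large components for speed)
  s1 <- if (nrow(rc1) > 400) rc1[seq(1, nrow(rc1), length.out = 400), ,
                                 drop = FALSE] else rc1
  s2 <- if (nrow(rc2) > 400) rc2[seq(1, nrow(rc2), length.out = 400), ,
                                 drop = FALSE] else rc2
  d2 <- outer(s1[, "row"], s2[, "row"], "-")^2 +
    outer(s1[, "col"], s2[, "col"], "-")^2
  k <- arrayInd(which.min(d2), dim(d2))
  c(x = unname((s1[k[1], "col"] + s2[k[2], "col"]) / 2),
    y = unname((s1[k[1], "row"] + s2[k[2], "row"]) / 2))
}

#' Geodesically farthest pixel of a component (root tip)
#'
#' Returns the pixel of the component most distant from `anchor` along
#' within-mask 8-connected paths with euclidean step costs. Ties resolve
#' to the smaller row, then smaller column.
#'
#' @param pixels linear pixel indices of the component.
#' @param anchor `c(x, y)` anchor position (inside or adjacent to the
#'   component).
#' @param shape image shape `c(rows, cols)`.
#' @return `c(x, y)` of the tip pixel.
#' @export
locate_tip <- function(pixels, anchor, shape) {
  if (!length(pixels)) stop("empty component")
  cm <- crop_mask(pixels, shape)
  rc <- cm$rc
  # seed: component pixel nearest the anchor
  d0 <- (rc[, "col"] - anchor[1])^2 + (rc[, "row"] - anchor[2])^2
  seed <- which.min(d0)
  geo <- geodesic_cpp(cm$mask,
                      cbind(rc[seed, "row"] - cm$r0 + 1,
                            rc[seed, "col"] - cm$c0 + 1), 0)
  dd <- geo$dist[cbind(rc[, "row"] - cm$r0 + 1, rc[, "col"] - cm$c0 + 1)]
  ord <- order(-dd, rc[, "row"], rc[, "col"])
  c(x = unname(rc[ord[1], "col"]), y = unname(rc[ord[1], "row"]))
}

component_depth_map <- function(cm) {
  # geodesic distance of each pixel of the cropped mask to the component
  # contour (ring of outside pixels adjacent to the component, distance 0);
  # image borders inside the crop also count as contour
  mask <- cm$mask
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- which(mask == 1L)
  rc <- cbind(row = ((inside - 1) %% nr) + 1,
              col = ((inside - 1) %/% nr) + 1)
  ring <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- rc[, "row"] + dr; c2 <- rc[, "col"] + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    lin <- r2[ok] + (c2[ok] - 1) * nr
    ring <- c(ring, lin[mask[lin] == 0L])
  }
  ring <- unique(ring)
  mask2 <- mask
  mask2[ring] <- 1L
  rcr <- cbind(((ring - 1) %% nr) + 1, ((ring - 1) %/% nr) + 1)
  geo <- geodesic_cpp(mask2, rcr, numeric(length(ring)))
  geo$dist
}

#' Trace the centerline between two points of a component
#'
#' Shortest 8-connected pixel path by Dijkstra, with step costs weighted
#' by `1 / (1 + min(D(a), D(b)))` where `D` is the distance map to the
#' component contour: deeper pixels are cheaper, pulling the path onto the
#' medial axis.
#'
#' @param p1,p2 `c(x, y)` endpoints (snapped to the nearest component
#'   pixel).
#' @param pixels linear pixel indices of the component.
#' @param shape image shape `c(rows, cols)`.
#' @return matrix of path coordinates (columns `x`, `y`), including both
#'   endpoints.
#' @export
trace_centerline <- function(p1, p2, pixels, shape) {
  cm <- crop_mask(pixels, shape)
  rc <- cm$rc
  snap <- function(p) {
    i <- which.min((rc[, "col"] - p[1])^2 + (rc[, "row"] - p[2])^2)
    c(rc[i, "row"] - cm$r0 + 1, rc[i, "col"] - cm$c0 + 1)
  }
  a <- snap(p1); b <- snap(p2)
  if (all(a == b))
    return(cbind(x = a[2] + cm$c0 - 1, y = a[1] + cm$r0 - 1))
  D <- component_depth_map(cm)
  D[!is.finite(D)] <- 0
  path <- grid_dijkstra_cpp(D, cm$mask, a[1], a[2],
                            matrix(b, 1, 2), 0L)
  if (!nrow(path))
    stop("endpoints lie in different connected parts of the component")
  cbind(x = path[, "col"] + cm$c0 - 1, y = path[, "row"] + cm$r0 - 1)
}

#' Douglas-Peucker polyline decimation
#'
#' @param pts matrix with columns x, y (>= 2 points).
#' @param tol_px perpendicular-distance tolerance; dropped points deviate
#'   by at most this from the decimated polyline.
#' @return the decimated point matrix (endpoints always kept).
#' @export
decimate_polyline <- function(pts, tol_px = 1.5) {
  n <- nrow(pts)
  stopifnot(n >= 2)
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  rec <- function(i0, i1) {
    if (i1 - i0 < 2) return(invisible())
    a <- pts[i0, ]; b <- pts[i1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i0 + 1):(i1 - 1)
    dp <- sweep(pts[idx, , drop = FALSE], 2, a)
    if (len2 == 0) {
      d <- sqrt(rowSums(dp^2))
    } else {
      cross <- abs(dp[, 1] * ab[2] - dp[, 2] * ab[1])
      d <- cross / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol_px) {
      keep[idx[k]] <<- TRUE
      rec(i0, idx[k])
      rec(idx[k], i1)
    }
    invisible()
  }
  rec(1, n)
  pts[keep, , drop = FALSE]
}

organ_from_chain <- function(chain, forest, S, cfg, parent_pixels = NULL) {
  # Build the timed centerline of one organ chain. Dual vertices: start
  # point (tip of the first component away from the first frontier, or the
  # attachment frontier for laterals), frontier points between consecutive
  # components (at exact observation times), and the geodesic tip of the
  # last component.
  G <- forest$graph
  nr <- G$shape[1]
  V <- G$vertices
  pix <- lapply(chain, function(id) G$pixels[[as.character(id)]])
  labs <- V$t[match(chain, V$id)]
  m <- length(chain)
  # frontier dual vertices w_1..w_{m-1}, times = label of the later
  # component minus one
  fr <- vector("list", max(m - 1, 0))
  if (m >= 2)
    for (i in seq_len(m - 1))
      fr[[i]] <- frontier_or_gap(pix[[i]], pix[[i + 1]], nr)
  t_fr <- if (m >= 2) pmax(labs[-1] - 1, 1) else numeric(0)
  # start vertex
  if (!is.null(parent_pixels)) {
    w0 <- locate_frontier_point(parent_pixels, pix[[1]], nr)
  } else if (m >= 2) {
    w0 <- locate_tip(pix[[1]], fr[[1]], G$shape)
  } else {
    # single isolated component: span its two geodesic extremes
    rc <- pix_rc(pix[[1]], nr)
    w0 <- locate_tip(pix[[1]], c(rc[1, "col"], rc[1, "row"]), G$shape)
  }
  t0 <- max(labs[1] - 1, 1)    # a region labelled 1 starts at the first
                               # observation (its earlier history is
                               # unobservable)
  # tip vertex
  anchor_tip <- if (m >= 2) fr[[m - 1]] else w0
  wtip <- locate_tip(pix[[m]], anchor_tip, G$shape)
  t_tip <- labs[m]
  nodes_x <- numeric(0); nodes_y <- numeric(0); nodes_t <- numeric(0)
  wpts <- c(list(w0), fr, list(wtip))
  wts <- c(t0, t_fr, t_tip)
  for (j in seq_len(length(wpts) - 1)) {
    comp <- pix[[j]]
    path <- trace_centerline(wpts[[j]], wpts[[j + 1]], comp, G$shape)
    if (nrow(path) >= 2) path <- decimate_polyline(path, cfg$dp_tol_px)
    # linear time interpolation along arc length between bounding vertices
    cl <- polyline_cumlen(path)
    tt <- if (max(cl) > 0)
      wts[j] + (wts[j + 1] - wts[j]) * cl / max(cl)
    else rep(wts[j], nrow(path))
    if (length(nodes_x)) { path <- path[-1, , drop = FALSE]; tt <- tt[-1] }
    nodes_x <- c(nodes_x, path[, 1])
    nodes_y <- c(nodes_y, path[, 2])
    nodes_t <- c(nodes_t, tt)
  }
  if (!length(nodes_x)) {
    nodes_x <- c(w0[1], wtip[1]); nodes_y <- c(w0[2], wtip[2])
    nodes_t <- c(t0, t_tip)
  }
  nodes_t <- cummax(nodes_t)   # guard monotonicity against snapping
  org <- root_organ(nodes_x, nodes_y, nodes_t)
  org$chain <- chain
  org
}

#' Build the timed root system model from an organ forest
#'
#' Converts each organ chain into a timed centerline: frontier points
#' between consecutive growth regions (exact observation times), a
#' geodesic tip per organ, distance-map-weighted shortest-path centerlines
#' through each region, Douglas-Peucker decimation, and linear time
#' interpolation of interior nodes. Lateral attachment nodes are the
#' frontier points between the lateral's first region and its parent's
#' region.
#'
#' @param forest a resolved `organ_forest`.
#' @param S the filtered [apparition_image()] (geometry source).
#' @param cfg a [geometry_config()].
#' @return a [root_system_model()]. Chains left detached by crossing
#'   resolution are still organ chains of the forest; they become laterals
#'   of the nearest plant (single-region remnants are dropped and counted
#'   in `attr(, "n_unattached_dropped")`).
#' @export
build_model <- function(forest, S, cfg = geometry_config()) {
  G <- forest$graph
  V <- G$vertices
  chains <- forest_organ_chains(forest)
  n_plants <- length(forest$sources)
  plants <- lapply(seq_len(n_plants), function(i)
    list(primary = NULL, laterals = list()))
  # plant assignment of detached chains: nearest primary-path centroid
  prim_pts <- lapply(seq_len(n_plants), function(p) {
    i <- which(V$role == "primary" & V$plant == p)
    cbind(V$cx[i], V$cy[i])
  })
  dropped <- 0
  for (ch in chains) {
    if (ch$order == 1) {
      org <- organ_from_chain(ch$chain, forest, S, cfg)
      org$order <- 1L
      org$id <- "p"
      plants[[ch$plant]]$primary <- org
      next
    }
    plant <- ch$plant
    parent_pix <- NULL
    if (ch$attached && !is.na(plant)) {
      parent_pix <- G$pixels[[as.character(ch$attached_to)]]
    } else {
      # detached chain: keep multi-region chains as organs of the
      # nearest plant; single isolated regions are noise remnants
      if (length(ch$chain) < 2) { dropped <- dropped + 1; next }
      i0 <- match(ch$chain[1], V$id)
      d <- vapply(prim_pts, function(pp)
        if (!nrow(pp)) Inf else
          min((pp[, 1] - V$cx[i0])^2 + (pp[, 2] - V$cy[i0])^2),
        numeric(1))
      plant <- which.min(d)
    }
    org <- organ_from_chain(ch$chain, forest, S, cfg,
                            parent_pixels = parent_pix)
    org$order <- 2L
    # insertion convention: laterals attach on the parent's centerline,
    # not at the edge of its rasterized tube
    prim <- plants[[plant]]$primary
    if (!is.null(parent_pix) && !is.null(prim)) {
      pr <- project_point_polyline(c(org$x[1], org$y[1]),
                                   cbind(prim$x, prim$y))
      if (pr$dist <= cfg$attach_snap_px &&
          (pr$point[1] != org$x[1] || pr$point[2] != org$y[1])) {
        org <- root_organ(c(pr$point[1], org$x), c(pr$point[2], org$y),
                          c(org$t[1], org$t), order = 2L,
                          extrapolated = c(FALSE, org$extrapolated),
                          id = org$id)
        org$chain <- ch$chain
      }
    }
    k <- length(plants[[plant]]$laterals) + 1
    org$id <- paste0("l", k)
    plants[[plant]]$laterals[[k]] <- org
  }
  model <- root_system_model(plants, G$px_size_um, G$timestep_h,
                             G$n_timesteps,
                             seed_row = cfg$seed_target_row %||% 1)
  attr(model, "n_unattached_dropped") <- dropped
  model
}

#' Extrapolate primary roots upstream to the seed line
#'
#' Prepends to each primary a minimum-cost pixel path (Dijkstra; step cost
#' = inter-pixel distance times the mean intensity of the two pixels) from
#' its detected initiation point up to `target_row`, following the dark
#' root remnants in the last frame. Added nodes carry the first node's
#' time and are flagged extrapolated.
#'
#' @param model a [root_system_model()].
#' @param last_frame intensity image of the last observation.
#' @param target_row image row of the seed line.
#' @param cfg a [geometry_config()].
#' @return the updated model.
#' @export
extrapolate_to_seed <- function(model, last_frame, target_row,
                                cfg = geometry_config()) {
  mask <- matrix(1L, nrow(last_frame), ncol(last_frame))
  targets <- cbind(rep(round(target_row), ncol(last_frame)),
                   seq_len(ncol(last_frame)))
  for (i in seq_along(model$plants)) {
    org <- model$plants[[i]]$primary
    if (is.null(org)) next
    y0 <- round(org$y[1]); x0 <- round(org$x[1])
    if (y0 <= target_row) next
    path <- grid_dijkstra_cpp(last_frame, mask, y0, x0, targets, 1L)
    if (!nrow(path)) next
    pts <- cbind(x = path[, "col"], y = path[, "row"])
    if (nrow(pts) >= 2) pts <- decimate_polyline(pts, cfg$dp_tol_px)
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]  # seed -> start
    if (nrow(pts) > 1) pts <- pts[-nrow(pts), , drop = FALSE]
    n_new <- nrow(pts)
    model$plants[[i]]$primary <- root_organ(
      c(pts[, 1], org$x), c(pts[, 2], org$y),
      c(rep(org$t[1], n_new), org$t),
      order = 1,
      extrapolated = c(rep(TRUE, n_new), org$extrapolated),
      id = org$id)
    model$plants[[i]]$primary$chain <- org$chain
  }
  model$seed_row <- target_row
  model
}

#' Keep, reject or extrapolate roots that stop before the last observation
#'
#' Isolated early-stopping roots are kept only when they grew over at
#' least `min_growth_timepoints` observations, and removed otherwise.
#' Roots whose last region touches an earlier root are assumed to continue
#' hidden below it: extrapolated nodes following the host's centerline at
#' the stopped root's median speed are appended until the last observation
#' or the host's end, flagged extrapolated.
#'
#' @param model a [root_system_model()] built by [build_model()].
#' @param forest the `organ_forest` (adjacency queried in the original
#'   graph).
#' @param cfg a [geometry_config()].
#' @return the updated model.
#' @export
handle_stopped_laterals <- function(model, forest,
                                    cfg = geometry_config()) {
  G <- forest$graph
  V <- G$vertices
  EF <- G$edges_full
  n_t <- model$n_timesteps
  # map every chained vertex to its organ for incidence lookup
  chains <- forest_organ_chains(forest)
  owner <- integer(0)
  for (k in seq_along(chains))
    owner[as.character(chains[[k]]$chain)] <- k
  organs_all <- model_organs(model)
  for (pi in seq_along(model$plants)) {
    keep <- logical(length(model$plants[[pi]]$laterals))
    for (li in seq_along(model$plants[[pi]]$laterals)) {
      org <- model$plants[[pi]]$laterals[[li]]
      keep[li] <- TRUE
      if (max(org$t) >= n_t - 1e-9) next
      chain <- org$chain
      last_v <- chain[length(chain)]
      nb <- c(EF$to[EF$from == last_v], EF$from[EF$to == last_v])
      nb_owner <- owner[as.character(nb)]
      other <- nb[!is.na(nb_owner) &
                    nb_owner != owner[as.character(last_v)]]
      # earlier root: neighbour region appeared at or before our stop
      other <- other[V$t[match(other, V$id)] <=
                       V$t[match(last_v, V$id)]]
      if (!length(other)) {
        n_tp <- length(unique(V$t[match(chain, V$id)]))
        if (n_tp < cfg$min_growth_timepoints) keep[li] <- FALSE
        next
      }
      # hidden continuation along the host organ
      host_k <- owner[as.character(other[1])]
      host <- chains[[host_k]]
      host_org <- NULL
      for (e in organs_all)
        if (identical(e$organ$chain, host$chain)) host_org <- e$organ
      if (is.null(host_org)) next
      # median speed of the stopped root, px per observation interval
      seg <- sqrt(diff(org$x)^2 + diff(org$y)^2)
      dtt <- diff(org$t)
      spd <- median(seg[dtt > 0] / dtt[dtt > 0])
      if (!is.finite(spd) || spd <= 0) next
      # nearest host node to the stopped tip, then follow host forward
      tipxy <- c(org$x[length(org$x)], org$y[length(org$y)])
      d <- (host_org$x - tipxy[1])^2 + (host_org$y - tipxy[2])^2
      j0 <- which.min(d)
      t_cur <- org$t[length(org$t)]
      xs <- numeric(0); ys <- numeric(0); ts <- numeric(0)
      j <- j0
      while (j < length(host_org$x) && t_cur < n_t) {
        j <- j + 1
        step <- sqrt((host_org$x[j] - ifelse(length(xs), xs[length(xs)],
                                             tipxy[1]))^2 +
                     (host_org$y[j] - ifelse(length(ys), ys[length(ys)],
                                             tipxy[2]))^2)
        t_cur <- min(t_cur + step / spd, n_t)
        xs <- c(xs, host_org$x[j]); ys <- c(ys, host_org$y[j])
        ts <- c(ts, t_cur)
      }
      if (length(xs)) {
        model$plants[[pi]]$laterals[[li]] <- root_organ(
          c(org$x, xs), c(org$y, ys), c(org$t, ts), order = 2,
          extrapolated = c(org$extrapolated, rep(TRUE, length(xs))),
          id = org$id)
        model$plants[[pi]]$laterals[[li]]$chain <- chain
      }
    }
    model$plants[[pi]]$laterals <- model$plants[[pi]]$laterals[keep]
  }
  model
}
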