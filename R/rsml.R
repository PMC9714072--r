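fmt_num <- function(x) sprintf("%.8g", x)

#' Write a root system model as RSML
#'
#' Produces RSML 1.0-structured XML: one scene, one plant per seedling,
#' first-order roots with laterals nested one level below, polyline
#' geometry in pixel coordinates (the pixel size is recorded in the
#' metadata), a per-polyline function `time` giving each node's continuous
#' observation index, and a function `extrapolated` (0/1 per node). Output
#' is deterministic: plants are ordered by seed position left to right and
#' laterals by attachment depth.
#'
#' @param model a [root_system_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(model, path) {
  for (e in model_organs(model)) {
    o <- e$organ
    if (length(o$x) < 2)
      stop(sprintf("organ %s of plant %d has fewer than 2 points",
                   e$organ_id, e$plant))
    if (length(o$t) != length(o$x) ||
        length(o$extrapolated) != length(o$x))
      stop(sprintf("organ %s of plant %d: function/point count mismatch",
                   e$organ_id, e$plant))
  }
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "pixel")
  xml2::xml_add_child(meta, "resolution", fmt_num(model$px_size_um))
  xml2::xml_add_child(meta, "software", "rhizotrack")
  props <- xml2::xml_add_child(meta, "property-definitions")
  tstep <- xml2::xml_add_child(meta, "time-sequence")
  xml2::xml_add_child(tstep, "unit", "hours")
  xml2::xml_add_child(tstep, "timestep", fmt_num(model$timestep_h))
  xml2::xml_add_child(tstep, "observations",
                      fmt_num(model$n_timesteps))
  invisible(props)
  scene <- xml2::xml_add_child(doc, "scene")
  # plants ordered by seed position (first primary node x)
  ord <- order(vapply(model$plants, function(p)
    if (is.null(p$primary)) Inf else p$primary$x[1], numeric(1)))
  add_organ <- function(parent, org, id) {
    rt <- xml2::xml_add_child(parent, "root", id = id,
                              label = if (org$order == 1) "primary"
                                      else "lateral")
    geom <- xml2::xml_add_child(rt, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (i in seq_along(org$x))
      xml2::xml_add_child(poly, "point", x = fmt_num(org$x[i]),
                          y = fmt_num(org$y[i]))
    fns <- xml2::xml_add_child(rt, "functions")
    ftime <- xml2::xml_add_child(fns, "function", name = "time",
                                 domain = "polyline")
    for (i in seq_along(org$t))
      xml2::xml_add_child(ftime, "sample", value = fmt_num(org$t[i]))
    fext <- xml2::xml_add_child(fns, "function", name = "extrapolated",
                                domain = "polyline")
    for (i in seq_along(org$extrapolated))
      xml2::xml_add_child(fext, "sample",
                          value = if (org$extrapolated[i]) "1" else "0")
    rt
  }
  for (k in seq_along(ord)) {
    p <- model$plants[[ord[k]]]
    pl <- xml2::xml_add_child(scene, "plant", id = as.character(k),
                              label = sprintf("plant_%d", k))
    if (is.null(p$primary)) next
    rt <- add_organ(pl, p$primary, sprintf("%d.p", k))
    lats <- p$laterals
    if (length(lats)) {
      lord <- order(vapply(lats, function(l) l$y[1], numeric(1)),
                    vapply(lats, function(l) l$t[1], numeric(1)))
      for (j in seq_along(lord))
        add_organ(rt, lats[[lord[j]]], sprintf("%d.l%d", k, j))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_organ <- function(node, order, n_t) {
  pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
  if (!length(pts))
    stop("root element without polyline geometry: id=",
         xml2::xml_attr(node, "id") %||% "?")
  x <- as.numeric(xml2::xml_attr(pts, "x"))
  y <- as.numeric(xml2::xml_attr(pts, "y"))
  tf <- xml2::xml_find_first(node,
                             "./functions/function[@name='time']")
  if (inherits(tf, "xml_missing")) {
    warning("RSML root without time function; assuming all nodes at t = ",
            n_t, call. = FALSE)
    tt <- rep(n_t, length(x))
  } else {
    sv <- xml2::xml_find_all(tf, "./sample")
    tt <- as.numeric(xml2::xml_attr(sv, "value"))
    if (length(tt) != length(x))
      stop(sprintf(paste0("function 'time' of root id=%s has %d samples ",
                          "for %d points"),
                   xml2::xml_attr(node, "id") %||% "?", length(tt),
                   length(x)))
  }
  ef <- xml2::xml_find_first(
    node, "./functions/function[@name='extrapolated']")
  ext <- if (inherits(ef, "xml_missing")) rep(FALSE, length(x)) else {
    sv <- xml2::xml_find_all(ef, "./sample")
    v <- xml2::xml_attr(sv, "value")
    if (length(v) != length(x))
      stop(sprintf(paste0("function 'extrapolated' of root id=%s has %d ",
                          "samples for %d points"),
                   xml2::xml_attr(node, "id") %||% "?", length(v),
                   length(x)))
    v == "1"
  }
  root_organ(x, y, tt, order = order, extrapolated = ext,
             id = xml2::xml_attr(node, "id"))
}

#' Read an RSML file into a root system model
#'
#' Parses this writer's dialect as well as plain time-free RSML (all nodes
#' are then placed at the last observation, with a warning).
#'
#' @param path RSML file.
#' @return a [root_system_model()].
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  get_meta_num <- function(xp, default) {
    n <- xml2::xml_find_first(doc, xp)
    if (inherits(n, "xml_missing")) default else
      as.numeric(xml2::xml_text(n))
  }
  px <- get_meta_num("./metadata/resolution", 19)
  tstep <- get_meta_num("./metadata/time-sequence/timestep", 8)
  n_t <- get_meta_num("./metadata/time-sequence/observations", 1)
  plants <- list()
  for (pl in xml2::xml_find_all(doc, "./scene/plant")) {
    roots1 <- xml2::xml_find_all(pl, "./root")
    if (!length(roots1)) next
    primary <- parse_organ(roots1[[1]], 1L, n_t)
    primary$id <- "p"
    laterals <- list()
    for (lt in xml2::xml_find_all(roots1[[1]], "./root")) {
      org <- parse_organ(lt, 2L, n_t)
      org$id <- paste0("l", length(laterals) + 1)
      laterals[[length(laterals) + 1]] <- org
    }
    plants[[length(plants) + 1]] <- list(primary = primary,
                                         laterals = laterals)
  }
  root_system_model(plants, px, tstep, as.integer(n_t))
}
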