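#' Rigid transform (rotation about the image center plus translation)
#'
#' Parameters describe the forward motion of the image content: a point `p`
#' (x = column, y = row) moves to `R(theta) (p - c) + c + (dx, dy)` where
#' `c` is the rotation center. Resampling and composition use the exact
#' inverse internally.
#'
#' @param theta rotation in radians (counter-clockwise in x/y pixel axes).
#' @param dx,dy translation in pixels.
#' @param center rotation center `c(x, y)`; usually the image center.
#' @return an `rt_rigid` object.
#' @export
rt_rigid <- function(theta = 0, dx = 0, dy = 0, center = c(0, 0)) {
  structure(list(theta = theta, dx = dx, dy = dy,
                 center = as.numeric(center)),
            class = "rt_rigid")
}

#' @export
print.rt_rigid <- function(x, ...) {
  cat(sprintf("<rt_rigid> theta = %.5f deg, d = (%.3f, %.3f) px\n",
              x$theta * 180 / pi, x$dx, x$dy))
  invisible(x)
}

rigid_as_linear <- function(tf) {
  R <- matrix(c(cos(tf$theta), sin(tf$theta),
                -sin(tf$theta), cos(tf$theta)), 2, 2)
  t_lin <- tf$center - R %*% tf$center + c(tf$dx, tf$dy)
  list(R = R, t = as.numeric(t_lin))
}

rigid_from_linear <- function(R, t, center = c(0, 0)) {
  theta <- atan2(R[2, 1], R[1, 1])
  d <- as.numeric(t - center + R %*% center)
  rt_rigid(theta, d[1], d[2], center)
}

#' Invert a rigid transform
#' @param tf an `rt_rigid`.
#' @return the inverse `rt_rigid` (same center).
#' @export
rigid_invert <- function(tf) {
  lin <- rigid_as_linear(tf)
  Ri <- t(lin$R)
  rigid_from_linear(Ri, as.numeric(-Ri %*% lin$t), tf$center)
}

#' Compose rigid transforms (`second` applied after `first`)
#' @param first,second `rt_rigid` objects.
#' @return the composed `rt_rigid`, expressed about `first`'s center.
#' @export
rigid_compose <- function(first, second) {
  l1 <- rigid_as_linear(first); l2 <- rigid_as_linear(second)
  rigid_from_linear(l2$R %*% l1$R,
                    as.numeric(l2$R %*% l1$t + l2$t), first$center)
}

# Forward-map points (n x 2 matrix, columns x, y).
rigid_apply <- function(tf, xy) {
  lin <- rigid_as_linear(tf)
  t(lin$R %*% t(xy)) + matrix(lin$t, nrow(xy), 2, byrow = TRUE)
}

#' Dense displacement field on a regular grid
#'
#' Backward residual displacements (sampling corrections applied before the
#' rigid part when resampling), bilinear-interpolated between grid nodes.
#'
#' @param grid_rows,grid_cols node coordinates (ascending, pixels).
#' @param vx,vy displacement components at the nodes
#'   (`length(grid_rows)` x `length(grid_cols)` matrices, pixels).
#' @return an `rt_dense` object.
#' @export
rt_dense <- function(grid_rows, grid_cols, vx, vy) {
  stopifnot(all(dim(vx) == c(length(grid_rows), length(grid_cols))),
            all(dim(vy) == dim(vx)), all(is.finite(vx)), all(is.finite(vy)))
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 vx = vx, vy = vy), class = "rt_dense")
}

dense_sample <- function(field, xy) {
  # bilinear interpolation of the field at arbitrary points; zero outside
  gr <- field$grid_rows; gc <- field$grid_cols
  hr <- if (length(gr) > 1) diff(gr)[1] else 1
  hc <- if (length(gc) > 1) diff(gc)[1] else 1
  mapr <- matrix((xy[, 2] - gr[1]) / hr + 1, ncol = 1)
  mapc <- matrix((xy[, 1] - gc[1]) / hc + 1, ncol = 1)
  vx <- bilinear_sample_cpp(field$vx, mapr, mapc, 0)
  vy <- bilinear_sample_cpp(field$vy, mapr, mapc, 0)
  cbind(as.numeric(vx), as.numeric(vy))
}

#' Pairwise frame transform (rigid plus optional dense correction)
#'
#' @param rigid an [rt_rigid()] (forward motion moving -> fixed).
#' @param dense optional [rt_dense()] backward correction on the fixed grid.
#' @return an `rt_transform`.
#' @export
rt_transform <- function(rigid, dense = NULL) {
  structure(list(rigid = rigid, dense = dense), class = "rt_transform")
}

# Backward evaluation: where in the moving image to sample for output
# location xy (fixed geometry). B(x) = B_rigid(x + v(x)).
transform_backward <- function(tf, xy) {
  if (inherits(tf, "rt_rigid")) tf <- rt_transform(tf)
  if (inherits(tf, "rt_chain")) {
    for (part in tf$parts) xy <- transform_backward(part, xy)
    return(xy)
  }
  stopifnot(inherits(tf, "rt_transform"))
  if (!is.null(tf$dense)) xy <- xy + dense_sample(tf$dense, xy)
  rigid_apply(rigid_invert(tf$rigid), xy)
}

#' Chain of pairwise transforms composed by function composition
#' @param parts list of `rt_transform`/`rt_rigid`, applied left to right on
#'   backward evaluation (nearest pairwise map first).
#' @return an `rt_chain`, collapsed to a single rigid transform when every
#'   part is purely rigid.
#' @export
rt_chain <- function(parts) {
  pure <- vapply(parts, function(p)
    inherits(p, "rt_rigid") ||
      (inherits(p, "rt_transform") && is.null(p$dense)), logical(1))
  if (all(pure)) {
    # Sequential backward evaluation applies parts[[1]]'s backward map
    # first, so the collapsed backward map is B_n o ... o B_1; store it as
    # a single forward rigid.
    rigids <- lapply(parts, function(p)
      if (inherits(p, "rt_rigid")) p else p$rigid)
    binv <- lapply(rigids, rigid_invert)        # backward maps
    comp <- binv[[1]]
    if (length(binv) > 1)
      for (i in 2:length(binv))
        comp <- rigid_compose(comp, binv[[i]])  # binv[[i]] applied after
    return(structure(list(rigid = rigid_invert(comp), dense = NULL),
                     class = "rt_transform"))
  }
  structure(list(parts = parts), class = "rt_chain")
}

#' Resample an image through a transform
#'
#' Applies the backward map in a single bilinear interpolation; the output
#' lives in the fixed geometry.
#'
#' @param image numeric matrix.
#' @param transform `rt_rigid`, `rt_transform` or `rt_chain`.
#' @param fill value for out-of-field pixels; default the image median
#'   (background level).
#' @return resampled numeric matrix, same shape.
#' @export
resample <- function(image, transform, fill = NULL) {
  fill <- fill %||% median(image)
  nr <- nrow(image); nc <- ncol(image)
  xy <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), nc))
  src <- transform_backward(transform, xy)
  mapr <- matrix(src[, 2], nr, nc)
  mapc <- matrix(src[, 1], nr, nc)
  bilinear_sample_cpp(image, mapr, mapc, fill)
}
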