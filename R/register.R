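#' Registration configuration
#'
#' Block-matching parameters. The similarity is normalized cross-correlation
#' on square blocks; blocks whose intensity variance falls below the
#' `min_var_quantile` quantile (with an absolute floor `min_var`) are
#' discarded before matching.
#'
#' @param block_half block half-size in px (block side is `2*block_half+1`).
#' @param stride grid spacing between block centers, px.
#' @param search_rigid,search_dense search radius in px for the rigid and
#'   dense stages.
#' @param coarse coarse search step, px.
#' @param min_var_quantile quantile of block variances under which blocks
#'   are dropped.
#' @param min_var absolute variance floor (gray^2).
#' @param min_ncc matches below this correlation are dropped.
#' @param trim_iter,trim_factor outlier trimming rounds in the rigid fit and
#'   the residual multiplier defining an outlier.
#' @param sigma_dense Gaussian regularization radius of the dense field, in
#'   grid cells.
#' @param max_disp displacement magnitude cap for the dense field, px.
#' @param ransac_tol inlier residual tolerance (px) of the robust rigid
#'   fit.
#' @param symmetric estimate both directions and average (cancels the
#'   small biases induced by root growth and resampling blur).
#' @param pyramid_factor downsampling factor of the coarse pyramid stage
#'   (1 disables the pyramid); large displacements are caught at coarse
#'   scale, then refined at full resolution within `refine_search` px.
#' @param refine_search search radius of the full-resolution refinement.
#' @return a list of class `register_config`.
#' @export
register_config <- function(block_half = 15, stride = 16, search_rigid = 40,
                            search_dense = 10, coarse = 3,
                            min_var_quantile = 0.7, min_var = 2,
                            min_ncc = 0.5, trim_iter = 4, trim_factor = 2.5,
                            sigma_dense = 2, max_disp = 10,
                            pyramid_factor = 2, refine_search = 8,
                            ransac_tol = 1.5, symmetric = TRUE) {
  structure(as.list(environment()), class = "register_config")
}

downsample_mean <- function(img, f) {
  if (f <= 1) return(img)
  nr <- (nrow(img) %/% f) * f
  nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  a <- array(img, c(f, nr / f, f, nc / f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

block_variance_threshold <- function(img, cfg) {
  # threshold on the structure-tensor energy of grid blocks: drop the
  # flattest blocks; 1-D (edge) blocks stay in and are handled by the
  # anisotropic fit
  v <- block_feature_cpp(img, cfg$block_half, cfg$stride, cfg$search_rigid)
  if (!length(v)) return(cfg$min_var)
  max(cfg$min_var, stats::quantile(v, cfg$min_var_quantile, names = FALSE))
}

fit_rigid_mixed <- function(src, dst, is2d, normals, center, cfg,
                            inliers = NULL) {
  # Gauss-Newton rigid fit dst ~ R(theta) (src - c) + c + d. Matches from
  # 2-D structured blocks contribute both residual components; matches
  # from 1-D (edge) blocks only the component along the edge normal (the
  # block may have slid along the edge).
  keep <- inliers %||% rep(TRUE, nrow(src))
  theta <- 0; d <- c(0, 0)
  k2 <- keep & is2d; k1 <- keep & !is2d
  for (it in 1:8) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    dR <- matrix(c(-sin(theta), cos(theta), -cos(theta), -sin(theta)), 2, 2)
    sc <- sweep(src, 2, center)
    pred <- t(R %*% t(sc)) + matrix(center + d, nrow(src), 2, byrow = TRUE)
    r <- pred - dst
    jth <- t(dR %*% t(sc))
    A <- matrix(0, 3, 3); b <- numeric(3)
    if (any(k2)) {
      J1 <- cbind(jth[k2, 1], 1, 0)
      J2 <- cbind(jth[k2, 2], 0, 1)
      A <- A + crossprod(J1) + crossprod(J2)
      b <- b + as.numeric(crossprod(J1, r[k2, 1]) + crossprod(J2, r[k2, 2]))
    }
    if (any(k1)) {
      Jn <- cbind(normals[k1, 1] * jth[k1, 1] + normals[k1, 2] * jth[k1, 2],
                  normals[k1, 1], normals[k1, 2])
      rn <- rowSums(normals[k1, , drop = FALSE] * r[k1, , drop = FALSE])
      A <- A + crossprod(Jn)
      b <- b + as.numeric(crossprod(Jn, rn))
    }
    if (abs(det(A)) < 1e-9) break
    delta <- solve(A, -b)
    theta <- theta + delta[1]
    d <- d + delta[2:3]
    if (max(abs(delta)) < 1e-10) break
  }
  fit <- rt_rigid(theta, d[1], d[2], center)
  # residuals: full for 2-D matches, edge-normal component for 1-D
  pred <- rigid_apply(fit, src)
  r <- pred - dst
  res <- ifelse(is2d, sqrt(rowSums(r^2)), abs(rowSums(normals * r)))
  list(fit = fit, res = res, keep = keep,
       rmse = sqrt(mean(res[keep]^2)))
}

fit_rigid_ransac <- function(src, dst, is2d, normals, center, cfg) {
  # 2-point rigid hypotheses from 2-D structured matches (deterministic
  # enumeration), scored against all matches (edge-normal residuals for
  # 1-D blocks), then a Gauss-Newton refit on the best consensus with one
  # trimming pass. Robust against blocks sliding along 1-D structures.
  n <- nrow(src)
  idx2 <- which(is2d)
  hyp_res <- function(theta, t0) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    pred <- t(R %*% t(src)) + matrix(t0, n, 2, byrow = TRUE)
    r <- pred - dst
    ifelse(is2d, sqrt(rowSums(r^2)), abs(rowSums(normals * r)))
  }
  best_inl <- NULL; best_score <- -1
  if (length(idx2) >= 2) {
    pairs <- t(utils::combn(idx2, 2))
    if (nrow(pairs) > 400)
      pairs <- pairs[seq(1, nrow(pairs), length.out = 400), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      vm <- src[j, ] - src[i, ]; vf <- dst[j, ] - dst[i, ]
      if (sum(vm^2) < 100) next               # short baseline
      theta <- atan2(vf[2], vf[1]) - atan2(vm[2], vm[1])
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      t0 <- dst[i, ] - as.numeric(R %*% src[i, ])
      res <- hyp_res(theta, t0)
      inl <- res < cfg$ransac_tol
      score <- 2 * sum(inl & is2d) + sum(inl & !is2d)
      if (score > best_score && sum(inl & is2d) >= 2) {
        best_score <- score
        best_inl <- inl
      }
    }
  }
  if (is.null(best_inl) || sum(best_inl) < 3) best_inl <- rep(TRUE, n)
  fit <- fit_rigid_mixed(src, dst, is2d, normals, center, cfg,
                         inliers = best_inl)
  # one trimming pass at the inlier tolerance
  keep <- fit$res < pmax(cfg$ransac_tol, 2.5 * median(fit$res[best_inl]))
  if (sum(keep) >= 3 && !identical(keep, best_inl))
    fit <- fit_rigid_mixed(src, dst, is2d, normals, center, cfg,
                           inliers = keep)
  fit
}

#' Estimate a rigid transform by block matching
#'
#' Finds block correspondences between `moving` and `fixed` (normalized
#' cross-correlation peak per block, coarse-to-fine with sub-pixel
#' refinement) and fits a rigid transform by least squares with iterative
#' outlier trimming.
#'
#' @param moving,fixed numeric matrices of identical shape.
#' @param cfg a [register_config()].
#' @return an [rt_rigid()] describing the forward motion moving -> fixed,
#'   with attributes `n_matches`, `n_used` and `rmse` (residual report).
#' @export
estimate_rigid_blockmatching <- function(moving, fixed,
                                         cfg = register_config()) {
  stopifnot(all(dim(moving) == dim(fixed)))
  if (isTRUE(cfg$symmetric)) {
    cfg1 <- cfg
    cfg1$symmetric <- FALSE
    fwd <- estimate_rigid_blockmatching(moving, fixed, cfg1)
    bwd <- estimate_rigid_blockmatching(fixed, moving, cfg1)
    binv <- rigid_invert(bwd)
    lf <- rigid_as_linear(fwd); lb <- rigid_as_linear(binv)
    theta <- (fwd$theta + binv$theta) / 2
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    out <- rigid_from_linear(R, (lf$t + lb$t) / 2, fwd$center)
    for (a in c("n_matches", "n_used", "n_2d", "rmse"))
      attr(out, a) <- attr(fwd, a)
    return(out)
  }
  if (cfg$pyramid_factor > 1) {
    f <- cfg$pyramid_factor
    cfg_c <- cfg
    cfg_c$pyramid_factor <- 1
    cfg_c$block_half <- max(8, round(cfg$block_half * 2 / 3))
    cfg_c$coarse <- 2
    coarse_fit <- estimate_rigid_blockmatching(
      downsample_mean(moving, f), downsample_mean(fixed, f), cfg_c)
    # rescale the coarse transform to full resolution
    est0 <- rt_rigid(coarse_fit$theta, coarse_fit$dx * f,
                     coarse_fit$dy * f, coarse_fit$center * f)
    aligned <- resample(moving, est0)
    cfg_r <- cfg
    cfg_r$pyramid_factor <- 1
    cfg_r$search_rigid <- cfg$refine_search
    est1 <- estimate_rigid_blockmatching(aligned, fixed, cfg_r)
    out <- rigid_compose(est0, est1)
    attr(out, "n_matches") <- attr(est1, "n_matches")
    attr(out, "n_used") <- attr(est1, "n_used")
    attr(out, "rmse") <- attr(est1, "rmse")
    return(out)
  }
  min_var <- block_variance_threshold(fixed, cfg)
  m <- block_match_cpp(moving, fixed, cfg$block_half, cfg$stride,
                       cfg$search_rigid, min_var, cfg$coarse)
  m <- m[m[, "ncc"] >= cfg$min_ncc, , drop = FALSE]
  if (nrow(m) < 3)
    stop("block matching failed: fewer than 3 valid correspondences (",
         nrow(m), " found)", call. = FALSE)
  center <- c((ncol(fixed) + 1) / 2, (nrow(fixed) + 1) / 2)
  # block at (cx, cy) in fixed matches moving at (cx+dx, cy+dy): the moving
  # point (cx+dx, cy+dy) moved forward onto the fixed point (cx, cy)
  pm <- cbind(m[, "cx"] + m[, "dx"], m[, "cy"] + m[, "dy"])
  pf <- cbind(m[, "cx"], m[, "cy"])
  is2d <- m[, "lmin"] >= 0.15 * m[, "lmax"]
  normals <- cbind(cos(m[, "gang"]), sin(m[, "gang"]))
  fit <- fit_rigid_ransac(pm, pf, is2d, normals, center, cfg)
  out <- fit$fit
  attr(out, "n_matches") <- nrow(m)
  attr(out, "n_used") <- sum(fit$keep)
  attr(out, "n_2d") <- sum(is2d)
  attr(out, "rmse") <- fit$rmse
  out
}

#' Estimate a dense correction field by block matching
#'
#' `moving` must already be rigid-aligned to `fixed`. Scattered block
#' displacements are smoothed by Gaussian-weighted averaging onto a regular
#' grid; grid nodes with no confident block nearby get a zero displacement.
#'
#' @inheritParams estimate_rigid_blockmatching
#' @return an [rt_dense()] backward field (zero everywhere when no block
#'   passes the confidence filters).
#' @export
estimate_dense_field <- function(moving, fixed, cfg = register_config()) {
  stopifnot(all(dim(moving) == dim(fixed)))
  cfg2 <- cfg
  cfg2$search_rigid <- cfg$search_dense     # margin bookkeeping
  min_var <- block_variance_threshold(fixed, cfg2)
  m <- block_match_cpp(moving, fixed, cfg$block_half, cfg$stride,
                       cfg$search_dense, min_var, min(cfg$coarse, 2))
  m <- m[m[, "ncc"] >= cfg$min_ncc, , drop = FALSE]
  gr <- seq(1, nrow(fixed), by = cfg$stride)
  gc <- seq(1, ncol(fixed), by = cfg$stride)
  vx <- matrix(0, length(gr), length(gc))
  vy <- matrix(0, length(gr), length(gc))
  if (nrow(m) > 0) {
    sigma <- cfg$sigma_dense * cfg$stride
    for (i in seq_along(gr)) {
      for (j in seq_along(gc)) {
        d2 <- (m[, "cx"] - gc[j])^2 + (m[, "cy"] - gr[i])^2
        w <- exp(-d2 / (2 * sigma^2))
        sw <- sum(w)
        if (sw > 0.1) {
          vx[i, j] <- sum(w * m[, "dx"]) / sw
          vy[i, j] <- sum(w * m[, "dy"]) / sw
        }
      }
    }
    mag <- sqrt(vx^2 + vy^2)
    over <- mag > cfg$max_disp
    if (any(over)) {
      scale <- ifelse(over, cfg$max_disp / mag, 1)
      vx <- vx * scale; vy <- vy * scale
    }
  }
  rt_dense(gr, gc, vx, vy)
}

#' Compose pairwise transforms into per-frame transforms (daisy chain)
#'
#' `pairwise[[i]]` maps frame i onto frame i+1; the reference is the last
#' frame, whose geometry is kept fixed. The result maps each frame onto the
#' last one and is applied in a single resampling.
#'
#' @param pairwise list of `N_t - 1` transforms ([rt_rigid()] or
#'   [rt_transform()]).
#' @return list of `N_t` transforms; entry `N_t` is the identity.
#' @export
compose_daisychain <- function(pairwise) {
  n_t <- length(pairwise) + 1
  out <- vector("list", n_t)
  out[[n_t]] <- rt_transform(rt_rigid())
  for (t in seq_len(n_t - 1)) {
    # backward evaluation must apply the pairwise map nearest the reference
    # first: frame N_t coords -> N_t-1 -> ... -> t
    out[[t]] <- rt_chain(rev(pairwise[t:(n_t - 1)]))
  }
  out
}

#' Register an image time series onto its last frame
#'
#' Estimates pairwise transforms between successive frames (rigid block
#' matching, optionally followed by a dense correction), composes them in a
#' daisy chain onto the last frame, and resamples every frame once.
#'
#' @param stack an [image_timeseries()].
#' @param cfg a [register_config()].
#' @param dense logical; also estimate the dense correction field.
#' @return the registered [image_timeseries()] with `$transforms` set to the
#'   composed per-frame transforms.
#' @export
register_timeseries <- function(stack, cfg = register_config(),
                                dense = FALSE) {
  n_t <- length(stack$frames)
  if (n_t < 2) stop("needs >=2 observations")
  pairwise <- vector("list", n_t - 1)
  for (t in seq_len(n_t - 1)) {
    moving <- stack$frames[[t]]
    fixed <- stack$frames[[t + 1]]
    rigid <- estimate_rigid_blockmatching(moving, fixed, cfg)
    fld <- NULL
    if (dense) {
      aligned <- resample(moving, rigid)
      fld <- estimate_dense_field(aligned, fixed, cfg)
    }
    pairwise[[t]] <- rt_transform(rigid, fld)
  }
  composed <- compose_daisychain(pairwise)
  frames <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    frames[[t]] <- if (t == n_t) stack$frames[[t]] else
      resample(stack$frames[[t]], composed[[t]])
  }
  out <- image_timeseries(frames, stack$timestep_h, stack$px_size_um,
                          transforms = composed)
  attr(out, "pairwise") <- pairwise
  out
}

#' Transforms expected from known simulator jitter
#'
#' Given the forward jitter transforms applied by the simulator to each
#' frame, returns the per-frame transforms a perfect registration onto the
#' last frame would recover.
#'
#' @param jitter list of `N_t` [rt_rigid()] forward jitter transforms.
#' @return list of `N_t` [rt_rigid()] transforms (last one the identity).
#' @export
expected_registration_transforms <- function(jitter) {
  n_t <- length(jitter)
  lapply(seq_len(n_t), function(t) {
    # frame t content was moved by jitter[[t]]; aligning it on the last
    # frame's geometry needs forward motion J_Nt o J_t^-1
    rigid_compose(rigid_invert(jitter[[t]]), jitter[[n_t]])
  })
}

#' Write registration transforms to a JSON sidecar
#'
#' Stores the per-frame composed transforms: rotation (radians),
#' translation (px), rotation center, and, when present, the dense
#' correction as a grid of displacements.
#'
#' @param transforms list of per-frame transforms (e.g.
#'   `register_timeseries(...)$transforms`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transforms_json <- function(transforms, path) {
  enc <- function(tf) {
    if (inherits(tf, "rt_chain"))
      return(list(kind = "chain", parts = lapply(tf$parts, enc)))
    rigid <- if (inherits(tf, "rt_rigid")) tf else tf$rigid
    out <- list(kind = "rigid", theta = rigid$theta,
                dx = rigid$dx, dy = rigid$dy, center = rigid$center)
    if (inherits(tf, "rt_transform") && !is.null(tf$dense))
      out$dense <- list(grid_rows = tf$dense$grid_rows,
                        grid_cols = tf$dense$grid_cols,
                        vx = tf$dense$vx, vy = tf$dense$vy)
    out
  }
  jsonlite::write_json(lapply(transforms, enc), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
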