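test_that("rigid block matching recovers identity, shifts and rotations", {
  img <- textured_image(260, 260, seed = 2)
  cfg <- register_config(search_rigid = 20, pyramid_factor = 1)
  ident <- estimate_rigid_blockmatching(img, img, cfg)
  expect_lt(abs(ident$dx), 0.25)
  expect_lt(abs(ident$dy), 0.25)
  expect_lt(abs(ident$theta) * 180 / pi, 0.05)

  shifted <- resample(img, rt_rigid(dx = 12, dy = -5))
  est <- estimate_rigid_blockmatching(img, shifted, cfg)
  expect_lt(abs(est$dx - 12), 0.5)
  expect_lt(abs(est$dy + 5), 0.5)

  center <- c((ncol(img) + 1) / 2, (nrow(img) + 1) / 2)
  rot <- resample(img, rt_rigid(theta = 1.5 * pi / 180, center = center))
  est2 <- estimate_rigid_blockmatching(img, rot, cfg)
  expect_lt(abs(est2$theta * 180 / pi - 1.5), 0.1)
})

test_that("degenerate inputs fail distinctly from identity", {
  flat <- matrix(100, 200, 200)
  expect_error(
    estimate_rigid_blockmatching(flat, flat,
                                 register_config(pyramid_factor = 1)),
    "fewer than 3 valid correspondences")
})

test_that("dense field is zero on identical or uniform pairs and recovers a known warp", {
  img <- textured_image(220, 220, seed = 5)
  cfg <- register_config()
  zero <- estimate_dense_field(img, img, cfg)
  expect_lt(max(abs(c(zero$vx, zero$vy))), 0.25)

  flat <- matrix(80, 220, 220)
  zf <- estimate_dense_field(flat, flat, cfg)
  expect_equal(max(abs(c(zf$vx, zf$vy))), 0)

  # known smooth warp, max |v| = 4 px
  nr <- nrow(img); nc <- ncol(img)
  gx <- outer(rep(1, nr), seq_len(nc))
  gy <- outer(seq_len(nr), rep(1, nc))
  wx <- 4 * sin(2 * pi * gy / nr)
  wy <- 4 * cos(2 * pi * gx / nc)
  warped <- bilinear_sample_cpp(img, gy + wy, gx + wx, median(img))
  est <- estimate_dense_field(warped, img, cfg)
  # the recovered backward field must recreate the sampling positions of
  # the applied warp: fixed(x) = warped(x + v) with v ~ -w
  interior <- expand.grid(x = seq(40, nc - 40, by = 8),
                          y = seq(40, nr - 40, by = 8))
  v <- rhizotrack:::dense_sample(est, as.matrix(interior))
  tx <- -4 * sin(2 * pi * interior$y / nr)
  ty <- -4 * cos(2 * pi * interior$x / nc)
  energy_true <- sum(tx^2 + ty^2)
  energy_err <- sum((v[, 1] - tx)^2 + (v[, 2] - ty)^2)
  expect_gt(1 - energy_err / energy_true, 0.8)
})

test_that("daisy-chain composition matches closed form and single resampling", {
  ident <- compose_daisychain(list(rt_rigid(), rt_rigid(), rt_rigid()))
  for (tf in ident) {
    xy <- cbind(c(1, 50, 99), c(1, 50, 99))
    expect_equal(rhizotrack:::transform_backward(tf, xy), xy,
                 tolerance = 1e-9)
  }

  steps <- list(rt_rigid(dx = 1), rt_rigid(dx = 1), rt_rigid(dx = 1))
  comp <- compose_daisychain(steps)
  xy <- cbind(c(10, 60), c(10, 60))
  back <- rhizotrack:::transform_backward(comp[[1]], xy)
  expect_equal(back, xy - cbind(c(3, 3), c(0, 0)), tolerance = 1e-9)

  # one composed resampling vs sequential resampling: positions of
  # isolated bright dots agree within half a pixel
  img <- matrix(0, 160, 160)
  dots <- cbind(c(40, 40, 120, 120), c(40, 120, 40, 120))
  for (k in 1:4) {
    rr <- dots[k, 1] + (-3:3); cc <- dots[k, 2] + (-3:3)
    img[rr, cc] <- img[rr, cc] +
      100 * exp(-(outer((-3:3)^2, (-3:3)^2, "+")) / 4)
  }
  t1 <- rt_rigid(theta = 0.01, dx = 2, dy = -1, center = c(80.5, 80.5))
  t2 <- rt_rigid(theta = -0.005, dx = -1, dy = 2, center = c(80.5, 80.5))
  once <- resample(img, rt_chain(list(t2, t1)), fill = 0)
  twice <- resample(resample(img, t1, fill = 0), t2, fill = 0)
  centroid_near <- function(im, p) {
    rr <- round(p[1]) + (-8:8); cc <- round(p[2]) + (-8:8)
    w <- im[rr, cc]
    c(sum(rr * rowSums(w)), sum(cc * colSums(w))) / sum(w)
  }
  for (k in 1:4) {
    c1 <- centroid_near(once, dots[k, ])
    c2 <- centroid_near(twice, dots[k, ])
    expect_lt(sqrt(sum((c1 - c2)^2)), 0.5)
  }
})

test_that("resampling is exact for identity, integer shifts and half-pixel edges", {
  img <- textured_image(60, 60, seed = 3)
  expect_equal(resample(img, rt_rigid()), img, tolerance = 1e-12)

  sh <- resample(img, rt_rigid(dx = 3, dy = 2))
  expect_equal(sh[10:50, 10:50], img[8:48, 7:47], tolerance = 1e-12)

  # step edge shifted by half a pixel: bilinear averages the two sides
  step <- matrix(0, 20, 20)
  step[, 11:20] <- 100
  half <- resample(step, rt_rigid(dx = 0.5), fill = 0)
  expect_equal(half[10, 11], 50)
  expect_equal(half[10, 13], 100)
})

test_that("transform inversion and composition are exact", {
  tf <- rt_rigid(theta = 0.2, dx = 5, dy = -3, center = c(50, 60))
  corners <- cbind(c(1, 1, 100, 100), c(1, 100, 1, 100))
  roundtrip <- rhizotrack:::rigid_apply(
    rigid_compose(tf, rigid_invert(tf)), corners)
  expect_lt(max(abs(roundtrip - corners)), 1e-9)
})

test_that("known rigid jitter on textured frames is recovered through the chain", {
  # scaled-down twin of the simulator-based recovery check in
  # test-acceptance.R: same estimation and composition machinery
  img <- textured_image(300, 300, seed = 21)
  center <- c(150.5, 150.5)
  set.seed(22)
  jit <- lapply(1:4, function(k)
    rt_rigid(theta = runif(1, -1, 1) * pi / 180,
             dx = runif(1, -10, 10), dy = runif(1, -10, 10),
             center = center))
  frames <- lapply(jit, function(j) resample(img, j))
  stk <- image_timeseries(frames)
  reg <- register_timeseries(stk, register_config(search_rigid = 30))
  expected <- expected_registration_transforms(jit)
  pts <- cbind(c(60, 60, 240, 240), c(60, 240, 60, 240))
  for (t in seq_along(expected)) {
    back_est <- rhizotrack:::transform_backward(reg$transforms[[t]], pts)
    back_exp <- rhizotrack:::rigid_apply(rigid_invert(expected[[t]]), pts)
    expect_lt(max(sqrt(rowSums((back_est - back_exp)^2))), 0.5)
    th <- if (inherits(reg$transforms[[t]], "rt_transform"))
      reg$transforms[[t]]$rigid$theta else reg$transforms[[t]]$theta
    expect_lt(abs(th - expected[[t]]$theta) * 180 / pi, 0.1)
  }
})
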