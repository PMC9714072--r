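test_that("per-pixel change-point detector applies both thresholds", {
  # no durable darkening: below the mean-shift threshold
  expect_equal(pixel_apparition_time(c(120, 119, 121, 120, 118, 122)), 0L)
  # clear step: label is the observation following the maximal drop
  expect_equal(pixel_apparition_time(c(120, 118, 121, 40, 38, 41)), 4L)
  # slow ramp passes the mean-shift test but has no sharp drop
  expect_equal(pixel_apparition_time(c(120, 111, 102, 93, 84, 75)), 0L)
  # tie on the maximal drop: earliest index wins
  expect_equal(pixel_apparition_time(c(100, 50, 50, 0, 0, 0)), 2L)
})

test_that("segment_stack recovers first-coverage frames on clean data", {
  p <- tiny_params(seed = 13, lateral_density = 0.2)
  stk <- rasterize_timeseries(simulate_architecture(p), p)
  S <- suppressWarnings(segment_stack(stk))
  expect_equal(dim(S), dim(stk$frames[[1]]))
  ct <- attr(stk, "coverage_time")
  d <- attr(stk, "tube_dist")
  # pixels with contrast >= s1 and first coverage after frame 1 must carry
  # the first covering frame as label
  prof <- rhizotrack:::root_profile(d, p$root_width_px, p$root_contrast)
  core <- is.finite(ct) & ct > 1 & prof >= 25
  expect_gt(sum(core), 1000)
  agree <- unclass(S)[core] == ceiling(ct[core] - 1e-9)
  expect_gt(mean(agree), 0.98)
  # all-constant stack segments to background
  flat <- image_timeseries(rep(list(matrix(150, 30, 30)), 5))
  expect_true(all(suppressWarnings(segment_stack(flat)) == 0))
})

test_that("noise changes few labels", {
  p0 <- tiny_params(seed = 14, lateral_density = 0.2)
  p1 <- tiny_params(seed = 14, lateral_density = 0.2, noise_sd = 3)
  s0 <- suppressWarnings(segment_stack(
    rasterize_timeseries(simulate_architecture(p0), p0)))
  s1 <- suppressWarnings(segment_stack(
    rasterize_timeseries(simulate_architecture(p1), p1)))
  expect_lt(mean(unclass(s0) != unclass(s1)), 0.02)
})

test_that("component filtering removes small components and is idempotent", {
  m <- matrix(0L, 80, 80)
  m[2:31, 2:51] <- 3L          # 30 x 50 = 1500 px, survives
  m[40:65, 2:51] <- 5L         # 26 x 50 = 1300 px, removed
  m[70:79, 2:51] <- 2L         # 10 x 50 =  500 px, removed
  S <- label_image(m, n_t = 6)
  f <- filter_components(S, min_component_px = 1400)
  expect_equal(sum(unclass(f) == 3L), 1500)
  expect_equal(sum(unclass(f) == 5L), 0)
  expect_equal(sum(unclass(f) == 2L), 0)
  expect_identical(unclass(filter_components(f, 1400)), unclass(f))
  # empty image passes through
  e <- label_image(matrix(0L, 10, 10), n_t = 3)
  expect_true(all(filter_components(e) == 0))
})

test_that("labels never exceed the number of observations", {
  p <- tiny_params(seed = 15)
  S <- suppressWarnings(segment_stack(
    rasterize_timeseries(simulate_architecture(p), p)))
  expect_lte(max(S), p$n_timesteps)
  # masks are nested by construction of the label semantics
  m5 <- unclass(S) > 0 & unclass(S) <= 5
  m9 <- unclass(S) > 0 & unclass(S) <= 9
  expect_true(all(m9[m5]))
})

test_that("the 2000 px filter corresponds to 38 mm of 1-px curve at 19 um/px", {
  expect_equal(component_threshold_mm(2000, 19), 38)
})
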