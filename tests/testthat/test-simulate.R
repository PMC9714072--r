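test_that("simulation is deterministic and respects lateral_density = 0", {
  p <- tiny_params(seed = 3)
  m1 <- simulate_architecture(p)
  m2 <- simulate_architecture(p)
  expect_identical(m1, m2)

  p0 <- tiny_params(seed = 3, lateral_density = 0)
  m0 <- simulate_architecture(p0)
  organs <- model_organs(m0)
  expect_length(organs, p0$n_plants)
  expect_true(all(vapply(organs, function(e) e$organ$order, integer(1)) ==
                    1L))
})

test_that("constant-rate primaries reach rate x elapsed-time arc length", {
  p <- sim_params(n_plants = 1, px_size_um = 150,
                  primary_rate = c(0.4, 0), tortuosity = 0,
                  lateral_density = 0, noise_sd = 0, jitter = c(0, 0),
                  artifact_rate = 0, seed = 5)
  m <- simulate_architecture(p)
  len_px <- rhizotrack:::polyline_length(rhizotrack:::organ_xy(m$plants[[1]]$primary))
  len_mm <- len_px * p$px_size_um / 1000
  # 0.4 mm/h over 20 intervals of 8 h = 64 mm
  expect_equal(len_mm, 64, tolerance = 0.02)
})

test_that("organ node times increase and laterals attach after the parent", {
  m <- simulate_architecture(tiny_params(seed = 11, lateral_density = 0.3))
  for (e in model_organs(m)) {
    expect_true(all(diff(e$organ$t) > 0))
  }
  for (p in m$plants) {
    for (l in p$laterals) {
      # the primary passed the attachment point before the lateral starts
      d <- sqrt((p$primary$x - l$x[1])^2 + (p$primary$y - l$y[1])^2)
      t_pass <- p$primary$t[which.min(d)]
      expect_lte(t_pass, l$t[1] + 1e-9)
    }
  }
})

test_that("an image too small for the requested growth is rejected", {
  expect_error(sim_params(px_size_um = 150, image_shape = c(100, 800)),
               "image too small")
})

test_that("rasterized coverage is nested over time (Russian dolls)", {
  p <- tiny_params(seed = 2)
  stk <- rasterize_timeseries(simulate_architecture(p), p)
  ct <- attr(stk, "coverage_time")
  masks <- lapply(1:3, function(k) ct <= k * 7)
  expect_true(all(masks[[1]] <= masks[[2]]))
  expect_true(all(masks[[2]] <= masks[[3]]))
  # noise- and jitter-free: frame pixel sets nested too (darker = covered)
  th <- p$background_level - 20
  for (k in seq_len(length(stk$frames) - 1)) {
    a <- stk$frames[[k]] < th
    b <- stk$frames[[k + 1]] < th
    expect_true(all(b[a]))
  }
})

test_that("centerline pixels take the full contrast drop", {
  p <- tiny_params(n_plants = 1, seed = 4)
  stk <- rasterize_timeseries(simulate_architecture(p), p)
  d <- attr(stk, "tube_dist")
  core <- which(d < 0.2 & attr(stk, "coverage_time") <= 21)
  expect_gt(length(core), 50)
  expect_true(all(stk$frames[[21]][core] ==
                    p$background_level - p$root_contrast))
})

test_that("rasterized mask length matches ground truth via an independent skeleton", {
  p <- sim_params(n_plants = 1, px_size_um = 200, tortuosity = 0.02,
                  lateral_density = 0, noise_sd = 0, jitter = c(0, 0),
                  artifact_rate = 0, seed = 9)
  m <- simulate_architecture(p)
  stk <- rasterize_timeseries(m, p)
  mask <- attr(stk, "coverage_time") <= p$n_timesteps
  # Zhang-Suen thinning (independent oracle, pure R)
  thin <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nr <- nrow(thin); nc <- ncol(thin)
      pad <- rbind(FALSE, cbind(FALSE, thin, FALSE), FALSE)
      P <- function(dr, dc) pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
      p2 <- P(-1, 0); p3 <- P(-1, 1); p4 <- P(0, 1); p5 <- P(1, 1)
      p6 <- P(1, 0); p7 <- P(1, -1); p8 <- P(0, -1); p9 <- P(-1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- thin & bsum >= 2 & bsum <= 6 & seqs == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- thin & bsum >= 2 & bsum <= 6 & seqs == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { thin[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  # skeleton path length through an independent graph library
  px <- which(thin, arr.ind = TRUE)
  d2 <- as.matrix(dist(px))
  adj <- d2 > 0 & d2 < 1.6
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = NULL)
  # weight edges by euclidean step length
  el <- matrix(as.integer(igraph::as_edgelist(g, names = FALSE)), ncol = 2)
  w <- sqrt(rowSums((px[el[, 1], ] - px[el[, 2], ])^2))
  g <- igraph::set_edge_attr(g, "weight", value = w)
  ends <- which(igraph::degree(g) == 1)
  sp <- igraph::distances(g, v = ends, to = ends)
  skel_len <- max(sp[is.finite(sp)])
  truth_len <- rhizotrack:::polyline_length(rhizotrack:::organ_xy(m$plants[[1]]$primary))
  expect_lt(abs(skel_len - truth_len) / truth_len, 0.05)
})

test_that("artifact injection is ledgered, persistent and removable", {
  p <- tiny_params(seed = 6, artifact_rate = 1)
  stk0 <- rasterize_timeseries(simulate_architecture(p), p)
  stk <- inject_artifacts(stk0, p)
  blobs <- attr(stk, "blobs")
  expect_gt(nrow(blobs), 0)
  # persistence: once a blob appears its pixels stay darker
  b <- blobs[1, ]
  rc <- cbind(round(b$row), round(b$col))
  for (k in seq(b$frame, length(stk$frames)))
    expect_lt(stk$frames[[k]][rc], stk0$frames[[k]][rc])
  # artifact_rate = 0 leaves the stack unchanged
  stk_same <- inject_artifacts(stk0, tiny_params(seed = 6))
  expect_identical(stk_same$frames, stk0$frames)
  # downstream segmentation + component filter removes isolated blobs
  S <- filter_components(suppressWarnings(segment_stack(stk)),
                         min_component_px = 760)
  ct <- attr(stk, "coverage_time")
  for (i in seq_len(nrow(blobs))) {
    rr <- round(blobs$row[i]) + (-15:15)
    cc <- round(blobs$col[i]) + (-15:15)
    rr <- rr[rr >= 1 & rr <= nrow(ct)]; cc <- cc[cc >= 1 & cc <= ncol(ct)]
    if (all(!is.finite(ct[rr, cc])))  # blob disc clear of any root
      expect_equal(unclass(S)[round(blobs$row[i]), round(blobs$col[i])],
                   0L)
  }
})
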