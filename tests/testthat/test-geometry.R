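test_that("frontier points sit mid-frontier with a deterministic tie-break", {
  nr <- 20
  # single shared pixel edge between (5,4) and (5,5)
  p1 <- 5 + (4 - 1) * nr
  p2 <- 5 + (5 - 1) * nr
  expect_equal(unname(locate_frontier_point(p1, p2, nr)), c(4.5, 5))
  # straight 5-edge frontier along a column interface, rows 10..14:
  # midpoint of the row-12 edge
  rows <- 10:14
  c1 <- rows + (6 - 1) * nr
  c2 <- rows + (7 - 1) * nr
  expect_equal(unname(locate_frontier_point(c1, c2, nr)), c(6.5, 12))
  # even frontier (4 edges, rows 10..13): lower-index median (row 11)
  rows <- 10:13
  expect_equal(unname(locate_frontier_point(rows + 5 * nr,
                                            rows + 6 * nr, nr))[2], 11)
  # non-adjacent components raise an error
  expect_error(locate_frontier_point(1, 45 + 9 * nr, nr), "not 4-adjacent")
})

test_that("tips are geodesically farthest, not euclidean-farthest", {
  nr <- 30
  # 1 x 10 horizontal bar at row 5, cols 3..12, anchored at its left end
  bar <- 5 + (3:12 - 1) * nr
  expect_equal(unname(locate_tip(bar, c(3, 5), c(nr, 30))), c(12, 5))
  # L-shape: long arm right, short arm down; from the right arm's end the
  # geodesically farthest pixel is the other arm's end even though a
  # mid-arm pixel can be euclidean-farther
  arm1 <- 5 + (3:20 - 1) * nr          # row 5, cols 3..20
  arm2 <- 6:14 + (3 - 1) * nr          # col 3, rows 6..14
  Lsh <- c(arm1, arm2)
  got <- locate_tip(Lsh, c(20, 5), c(nr, 30))
  # brute-force geodesic via igraph on the mask lattice
  rc <- rhizotrack:::pix_rc(Lsh, nr)
  d2 <- as.matrix(dist(rc))
  adj <- d2 > 0 & d2 < 1.6
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  el <- matrix(as.integer(igraph::as_edgelist(g, names = FALSE)), ncol = 2)
  g <- igraph::set_edge_attr(g, "weight",
                             value = sqrt(rowSums((rc[el[, 1], ] -
                                                     rc[el[, 2], ])^2)))
  anchor_i <- which(rc[, "col"] == 20 & rc[, "row"] == 5)
  dd <- igraph::distances(g, v = anchor_i)
  far <- rc[which.max(dd), ]
  expect_equal(unname(got), unname(c(far["col"], far["row"])))
  # single-pixel component is its own tip
  expect_equal(unname(locate_tip(7 + 7 * nr, c(99, 99), c(nr, 30))),
               c(8, 7))
})

test_that("centerlines follow the medial axis of a wide component", {
  nr <- 12
  # 3-px-wide horizontal bar, rows 5..7, cols 2..11
  pix <- as.integer(outer(5:7, (2:11 - 1) * nr, "+"))
  path <- trace_centerline(c(2, 6), c(11, 6), pix, c(nr, 12))
  expect_true(all(path[, "y"] == 6))       # stays on the central row
  # 1-px path: unique
  thin <- 3 + (2:9 - 1) * nr
  p2 <- trace_centerline(c(2, 3), c(9, 3), thin, c(nr, 12))
  expect_equal(nrow(p2), 8)
  # p1 == p2: single point
  expect_equal(nrow(trace_centerline(c(5, 6), c(5, 6), pix, c(nr, 12))), 1)
  # endpoints in disconnected parts raise an error
  two <- c(5 + (2 - 1) * nr, 5 + (9 - 1) * nr)
  expect_error(trace_centerline(c(2, 5), c(9, 5), two, c(nr, 12)),
               "different connected parts")
})

test_that("Douglas-Peucker keeps deviating points and bounds the error", {
  pts <- cbind(c(0, 5, 10), c(0, 5, 10))
  expect_equal(nrow(decimate_polyline(pts, 1)), 2)
  bump <- cbind(c(0, 5, 10), c(0, 4, 0))
  expect_equal(nrow(decimate_polyline(bump, 1)), 3)    # deviation 4 > 1
  expect_equal(nrow(decimate_polyline(bump, 5)), 2)    # 4 <= 5
  # Hausdorff bound property on random polylines
  set.seed(19)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    poly <- cbind(cumsum(runif(n, 0.5, 2)), cumsum(rnorm(n, 0, 1.5)))
    tol <- runif(1, 0.5, 4)
    dec <- decimate_polyline(poly, tol)
    d <- vapply(seq_len(n), function(i)
      rhizotrack:::project_point_polyline(poly[i, ], dec)$dist, numeric(1))
    expect_lte(max(d), tol + 1e-9)
  }
})

test_that("reconstructed organs match simulated geometry and times", {
  p <- sim_params(n_plants = 1, px_size_um = 150, tortuosity = 0.02,
                  lateral_density = 0, noise_sd = 0, jitter = c(0, 0),
                  artifact_rate = 0, seed = 33)
  m <- simulate_architecture(p)
  stk <- rasterize_timeseries(m, p)
  S <- filter_components(suppressWarnings(segment_stack(stk)), 700)
  rec <- reconstruct_architecture(S, 1, geometry_cfg = geometry_config(
    seed_target_row = m$seed_row))
  est <- rec$model$plants[[1]]$primary
  truth <- m$plants[[1]]$primary
  len_est <- root_length_at(rec$model, 1, "p", p$n_timesteps)
  len_truth <- rhizotrack:::organ_length_at(truth, p$n_timesteps,
                                            p$px_size_um, FALSE)
  expect_lt(abs(len_est - len_truth) / len_truth, 0.03)
  # node times within half an observation of the truth's passage times
  obs <- !est$extrapolated
  for (i in which(obs)) {
    d <- sqrt((truth$x - est$x[i])^2 + (truth$y - est$y[i])^2)
    expect_lt(abs(truth$t[which.min(d)] - est$t[i]), 0.5)
  }
  # tortuous polylines are at least as long as the straight chord
  chord <- sqrt(diff(range(est$x))^2 + diff(range(est$y))^2)
  expect_gte(len_est * 1000 / p$px_size_um + 1e-6, chord)
})

test_that("single-growth organs become two-node polylines", {
  m <- matrix(0L, 20, 12)
  m[2:6, 5:7] <- 1L
  m[7:14, 5:7] <- 2L
  G <- extract_primaries(build_rag(label_image(m, 2)), 1)
  fo <- prune_to_forest(G)
  model <- build_model(fo, label_image(m, 2))
  org <- model$plants[[1]]$primary
  expect_gte(length(org$x), 2)
  expect_equal(org$t[1], 1)            # organ origin at the first frame
  expect_equal(max(org$t), 2)
})

test_that("seed extrapolation follows dark paths and flags its nodes", {
  img <- matrix(200, 40, 30)
  img[5:30, 14] <- 40                  # dark vertical line
  model <- root_system_model(list(list(
    primary = root_organ(c(14, 15), c(30, 38), c(1, 2)),
    laterals = list())), 150, 8, 2, seed_row = 5)
  out <- extrapolate_to_seed(model, img, target_row = 5)
  org <- out$plants[[1]]$primary
  expect_true(any(org$extrapolated))
  pre <- which(org$extrapolated)
  expect_true(all(abs(org$x[pre] - 14) <= 1))   # hugs the dark line
  expect_equal(min(org$y[pre]), 5)
  expect_true(all(org$t[pre] == org$t[max(pre) + 1]))
  # already at the target row: no-op
  m2 <- root_system_model(list(list(
    primary = root_organ(c(10, 10), c(5, 20), c(1, 2)),
    laterals = list())), 150, 8, 2, seed_row = 5)
  expect_identical(extrapolate_to_seed(m2, img, 5)$plants,
                   m2$plants)
  # uniform background: straight vertical path
  flat <- matrix(200, 40, 30)
  out3 <- extrapolate_to_seed(model, flat, target_row = 5)
  org3 <- out3$plants[[1]]$primary
  pre3 <- which(org3$extrapolated)
  expect_true(all(abs(org3$x[pre3] - org3$x[max(pre3) + 1]) <= 1))
})

test_that("stopped isolated laterals are kept or removed by growth duration", {
  p <- tiny_params(seed = 61, n_plants = 2, lateral_density = 0.3,
                   lateral_stop_prob = 0.5)
  stk <- rasterize_timeseries(simulate_architecture(p), p)
  S <- filter_components(suppressWarnings(segment_stack(stk)), 700)
  G <- extract_primaries(build_rag(S), 2)
  fo <- reject_artefact_roots(resolve_crossings(prune_to_forest(G), G))
  model <- build_model(fo, S)
  before <- model
  after <- handle_stopped_laterals(model, fo)
  V <- G$vertices
  for (pi in seq_along(before$plants)) {
    for (org in before$plants[[pi]]$laterals) {
      n_tp <- length(unique(V$t[match(org$chain, V$id)]))
      still <- any(vapply(after$plants[[pi]]$laterals, function(o)
        identical(o$chain, org$chain), logical(1)))
      if (max(org$t) >= p$n_timesteps - 1e-9) {
        expect_true(still)             # organs reaching the end are kept
      } else if (!still) {
        # removed organs must be short-lived isolated stoppers
        expect_lt(n_tp, 3)
      }
    }
  }
  # any extrapolated tail nodes are flagged and non-decreasing in time
  for (pi in seq_along(after$plants))
    for (org in after$plants[[pi]]$laterals)
      expect_true(all(diff(org$t) > -1e-9))
})
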