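two_segment_model <- function() {
  # polyline with one 3 mm segment appearing at t=2 and one 4 mm segment
  # appearing at t=3 (19 um/px: 1 mm = 52.631... px)
  px_per_mm <- 1000 / 19
  prim <- root_organ(c(10, 10, 10), c(0, 3 * px_per_mm, 7 * px_per_mm),
                     c(1, 2, 3))
  root_system_model(list(list(primary = prim, laterals = list())),
                    px_size_um = 19, timestep_h = 8, n_timesteps = 3)
}

test_that("root length accumulates segments by apparition time", {
  m <- two_segment_model()
  expect_equal(root_length_at(m, 1, "p", 0.5), 0)
  expect_equal(root_length_at(m, 1, "p", 2), 3)
  expect_equal(root_length_at(m, 1, "p", 3), 7)
  expect_equal(root_length_at(m, 1, "p", m$n_timesteps),
               root_length_at(m, 1, "p", 99))
  expect_error(root_length_at(m, 1, "l9", 2), "unknown organ")
})

test_that("growth telescopes to the total length", {
  m <- two_segment_model()
  expect_equal(growth_between(m, 1, "p", 2, 3), 4)
  g <- vapply(2:3, function(t) growth_between(m, 1, "p", t - 1, t),
              numeric(1))
  expect_equal(sum(g) + root_length_at(m, 1, "p", 1),
               root_length_at(m, 1, "p", 3))
  # lengths scale linearly with the configured pixel size
  m2 <- m
  m2$px_size_um <- 38
  expect_equal(root_length_at(m2, 1, "p", 3),
               2 * root_length_at(m, 1, "p", 3))
})

test_that("per-organ length is non-decreasing in time on simulated data", {
  m <- simulate_architecture(tiny_params(seed = 71, lateral_density = 0.3))
  tab <- phene_table(m)
  for (org in split(tab, paste(tab$plant, tab$organ))) {
    expect_true(all(diff(org$length_mm) >= -1e-9))
    expect_equal(sum(org$growth_mm), org$length_mm[nrow(org)])
  }
})

test_that("lateral counts follow the emergence schedule", {
  m <- simulate_architecture(tiny_params(seed = 72, lateral_density = 0.3))
  sched <- sort(unlist(lapply(m$plants, function(p)
    vapply(p$laterals, function(l) l$t[1], numeric(1)))))
  expect_equal(count_laterals(m, 1), 0)
  for (t in c(5, 9, 13, 17, 21))
    expect_equal(count_laterals(m, t), sum(sched <= t + 1e-9))
  expect_equal(count_laterals(m, m$n_timesteps), length(sched))
})

test_that("elongation heatmaps place laterals by insertion depth", {
  px_per_mm <- 1000 / 150
  prim <- root_organ(c(50, 50, 50, 50), c(10, 100, 200, 300), 1:4)
  lat <- root_organ(c(50, 60, 70, 80), 10 + 20 * px_per_mm + c(0, 1, 2, 3),
                    1:4, order = 2)
  m <- root_system_model(list(list(primary = prim,
                                   laterals = list(lat))),
                         150, 8, 4, seed_row = 10)
  hm <- elongation_heatmap(list(m), depth_bins = c(0, 15, 30, 45))
  expect_s3_class(autoplot(hm), "ggplot")
  # insertion at 20 mm: only the 15-30 bin is populated
  pop <- rowSums(hm$n)
  expect_true(pop[2] > 0 && pop[1] == 0 && pop[3] == 0)
  # constant rate: populated cells all equal
  vals <- hm$heatmap[2, is.finite(hm$heatmap[2, ])]
  expect_equal(diff(range(vals)), 0, tolerance = 1e-9)
  # two identical populations give identical heatmaps
  hm2 <- elongation_heatmap(list(m, m), depth_bins = c(0, 15, 30, 45))
  expect_equal(hm$heatmap, hm2$heatmap)
})

test_that("Mann-Whitney group tests behave at the extremes and match pair counts", {
  a <- matrix(rep(c(1, 2, 3, 4, 5), 2), 5, 2)
  same <- per_timestep_group_test(a, a)
  expect_true(all(same$p_value == 1))
  set.seed(4)
  lo <- matrix(runif(60, 0, 1), 30, 2)
  hi <- matrix(runif(60, 5, 6), 30, 2)
  sep <- per_timestep_group_test(lo, hi)
  expect_true(all(sep$p_value < 0.001))
  # U equals brute-force pair counting for n <= 8
  for (seed in 1:20) {
    set.seed(seed)
    x <- round(runif(sample(3:8, 1), 0, 10), 2)
    y <- round(runif(sample(3:8, 1), 0, 10), 2)
    res <- per_timestep_group_test(matrix(x), matrix(y))
    u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(res$statistic), u_brute)
  }
  # insufficient samples yield NA, not an error
  tiny <- per_timestep_group_test(matrix(1:2), matrix(1:5))
  expect_true(is.na(tiny$p_value))
})

test_that("tidiers and summaries expose the published aggregations", {
  m <- simulate_architecture(tiny_params(seed = 73, lateral_density = 0.25))
  tab <- tidy(m)
  expect_s3_class(tab, "tbl_df")
  expect_true(all(c("plant", "organ", "time", "length_mm", "growth_mm") %in%
                    names(tab)))
  s <- length_summary(list(m))
  expect_equal(s$trait, c("primary_length_mm", "lateral_total_length_mm",
                          "lateral_mean_length_mm"))
  g <- glance(m)
  expect_equal(g$n_plants, 2)
  expect_s3_class(autoplot(m), "ggplot")
})
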