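get_organ <- function(model, plant, organ_id) {
  p <- model$plants[[plant]]
  if (is.null(p)) stop("unknown plant ", plant)
  if (organ_id %in% c("p", "primary")) return(p$primary)
  for (l in p$laterals) if (identical(l$id, organ_id)) return(l)
  stop(sprintf("unknown organ '%s' of plant %d", organ_id, plant))
}

organ_length_at <- function(org, t, px_size_um, include_extrapolated) {
  if (length(org$x) < 2) return(0)
  seg <- sqrt(diff(org$x)^2 + diff(org$y)^2)
  app <- org$t[-1]                        # segment apparition = later node
  use <- app <= t + 1e-9
  if (!include_extrapolated) use <- use & !org$extrapolated[-1]
  sum(seg[use]) * px_size_um / 1000
}

#' Root length at a given observation time
#'
#' Sum of the centerline segment lengths whose apparition time (the time
#' of the segment's later node) is at or before `t`, converted to mm.
#' Extrapolated segments are excluded unless requested.
#'
#' @param model a [root_system_model()].
#' @param plant plant index.
#' @param organ organ identifier (`"p"` for the primary, `"l1"`,
#'   `"l2"`, ... for laterals).
#' @param t observation time (may be fractional).
#' @param include_extrapolated count extrapolated segments too.
#' @return length in mm.
#' @export
root_length_at <- function(model, plant, organ, t,
                           include_extrapolated = FALSE) {
  org <- get_organ(model, plant, organ)
  organ_length_at(org, t, model$px_size_um, include_extrapolated)
}

#' Growth of a root between two observation times
#'
#' @inheritParams root_length_at
#' @param t1,t2 observation times, `t1 < t2`.
#' @return `root_length_at(t2) - root_length_at(t1)`, in mm (>= 0).
#' @export
growth_between <- function(model, plant, organ, t1, t2,
                           include_extrapolated = FALSE) {
  stopifnot(t1 < t2)
  root_length_at(model, plant, organ, t2, include_extrapolated) -
    root_length_at(model, plant, organ, t1, include_extrapolated)
}

#' Number of emerged lateral roots at time t
#'
#' Counts order-2 organs whose first node time is at or before `t`.
#'
#' @param model a [root_system_model()].
#' @param t observation time.
#' @param plant optional plant index; all plants when `NULL`.
#' @return integer count.
#' @export
count_laterals <- function(model, t, plant = NULL) {
  plants <- if (is.null(plant)) model$plants else model$plants[plant]
  sum(vapply(plants, function(p)
    sum(vapply(p$laterals, function(l) l$t[1] <= t + 1e-9, logical(1))),
    integer(1)))
}

#' Tidy phene table of a model
#'
#' One row per organ and observation: length, per-interval growth, tip
#' depth and (for laterals) insertion depth, all in mm from the seed line.
#'
#' @param model a [root_system_model()].
#' @param times observation times to evaluate (default `1..N_t`).
#' @param plate plate identifier copied into the table.
#' @param include_extrapolated count extrapolated segments.
#' @return a tibble with columns plate, plant, organ, order, time,
#'   length_mm, growth_mm, tip_depth_mm, insertion_depth_mm.
#' @export
phene_table <- function(model, times = seq_len(model$n_timesteps),
                        plate = 1L, include_extrapolated = FALSE) {
  px_mm <- model$px_size_um / 1000
  rows <- list()
  for (pi in seq_along(model$plants)) {
    p <- model$plants[[pi]]
    organs <- c(list(p$primary), p$laterals)
    for (org in organs) {
      if (is.null(org)) next
      lens <- vapply(times, function(t)
        organ_length_at(org, t, model$px_size_um, include_extrapolated),
        numeric(1))
      obs <- !org$extrapolated
      tip_d <- vapply(times, function(t) {
        i <- which(org$t <= t + 1e-9 & obs)
        if (!length(i)) NA_real_ else
          (org$y[max(i)] - model$seed_row) * px_mm
      }, numeric(1))
      rows[[length(rows) + 1]] <- tibble(
        plate = plate, plant = pi, organ = org$id %||% "?",
        order = org$order, time = times, length_mm = lens,
        growth_mm = c(lens[1], diff(lens)),
        tip_depth_mm = tip_d,
        insertion_depth_mm = if (org$order == 2)
          (org$y[1] - model$seed_row) * px_mm else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
tidy.root_system_model <- function(x, ...) phene_table(x, ...)

#' Depth-binned lateral elongation heatmap
#'
#' Assigns laterals to bins by insertion depth (mm from the seed line) and
#' averages, over the population of models, the per-interval elongation
#' rate of the laterals in each bin. Cells without any lateral are `NA`
#' (distinct from observed zero growth). Also reports the mean and sd of
#' primary tip depth per time.
#'
#' @param models list of [root_system_model()]s.
#' @param depth_bins bin edges in mm.
#' @param times observation times (default union grid `2..N_t`).
#' @return list with `heatmap` (depth bin x time matrix of mean elongation
#'   mm/interval), `n` (same shape, population counts), and `primary_tip`
#'   (tibble: time, mean_mm, sd_mm); class `elongation_heatmap`.
#' @export
elongation_heatmap <- function(models, depth_bins = seq(0, 100, by = 15),
                               times = NULL) {
  stopifnot(length(models) >= 1)
  n_t <- models[[1]]$n_timesteps
  times <- times %||% seq(2, n_t)
  tabs <- dplyr::bind_rows(lapply(seq_along(models), function(i)
    phene_table(models[[i]], plate = i)))
  lat <- tabs[tabs$order == 2 & tabs$time %in% times, ]
  lat$bin <- cut(lat$insertion_depth_mm, depth_bins, right = FALSE)
  nb <- length(depth_bins) - 1
  H <- matrix(NA_real_, nb, length(times),
              dimnames = list(levels(lat$bin), times))
  N <- matrix(0L, nb, length(times), dimnames = dimnames(H))
  # only intervals after the lateral emerged contribute
  lat <- lat[!is.na(lat$bin) & lat$length_mm > 0, ]
  if (nrow(lat)) {
    agg <- dplyr::summarise(
      dplyr::group_by(lat, .data$bin, .data$time),
      rate = mean(.data$growth_mm), n = dplyr::n(), .groups = "drop")
    H[cbind(as.integer(agg$bin), match(agg$time, times))] <- agg$rate
    N[cbind(as.integer(agg$bin), match(agg$time, times))] <- agg$n
  }
  prim <- tabs[tabs$order == 1, ]
  tip <- dplyr::summarise(dplyr::group_by(prim, .data$time),
                          mean_mm = mean(.data$tip_depth_mm, na.rm = TRUE),
                          sd_mm = sd(.data$tip_depth_mm, na.rm = TRUE),
                          .groups = "drop")
  structure(list(heatmap = H, n = N, primary_tip = tip,
                 depth_bins = depth_bins, times = times),
            class = "elongation_heatmap")
}

#' Per-timestep two-group comparison (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test per timestep between two groups of
#' per-plant growth values (exact null distribution for small samples
#' without ties, normal approximation with tie correction otherwise, as
#' implemented by [stats::wilcox.test()]).
#'
#' @param groupA,groupB matrices or data frames of growth values, one row
#'   per individual and one column per timestep.
#' @param min_n minimum samples per group and timestep; smaller yields NA.
#' @return tibble with columns time, n_a, n_b, statistic (U), p_value.
#' @export
per_timestep_group_test <- function(groupA, groupB, min_n = 3) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  stopifnot(ncol(groupA) == ncol(groupB))
  res <- lapply(seq_len(ncol(groupA)), function(j) {
    a <- groupA[, j]; b <- groupB[, j]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < min_n || length(b) < min_n)
      return(tibble(time = j, n_a = length(a), n_b = length(b),
                    statistic = NA_real_, p_value = NA_real_))
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL,
                                       correct = TRUE))
    tibble(time = j, n_a = length(a), n_b = length(b),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  dplyr::bind_rows(res)
}

#' Summary statistics of primary and lateral root length per plant
#'
#' Terminal-architecture group summary: per-plant primary length and both
#' per-plant total and per-root mean lateral length (the two published
#' aggregations), with population mean and sd.
#'
#' @param models list of [root_system_model()]s.
#' @param t observation time (default last).
#' @return tibble with one row per trait: trait, mean, sd, n.
#' @export
length_summary <- function(models, t = NULL) {
  rows <- list()
  for (m in models) {
    tt <- t %||% m$n_timesteps
    for (pi in seq_along(m$plants)) {
      p <- m$plants[[pi]]
      if (is.null(p$primary)) next
      prim <- organ_length_at(p$primary, tt, m$px_size_um, FALSE)
      lat <- vapply(p$laterals, organ_length_at, numeric(1), t = tt,
                    px_size_um = m$px_size_um,
                    include_extrapolated = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        primary_mm = prim,
        lateral_total_mm = sum(lat),
        lateral_mean_mm = if (length(lat)) mean(lat) else NA_real_)
    }
  }
  per_plant <- dplyr::bind_rows(rows)
  tibble(
    trait = c("primary_length_mm", "lateral_total_length_mm",
              "lateral_mean_length_mm"),
    mean = c(mean(per_plant$primary_mm),
             mean(per_plant$lateral_total_mm),
             mean(per_plant$lateral_mean_mm, na.rm = TRUE)),
    sd = c(sd(per_plant$primary_mm), sd(per_plant$lateral_total_mm),
           sd(per_plant$lateral_mean_mm, na.rm = TRUE)),
    n = nrow(per_plant))
}

#' @export
glance.root_system_model <- function(x, ...) {
  nl <- vapply(x$plants, function(p) length(p$laterals), integer(1))
  s <- length_summary(list(x))
  tibble(n_plants = length(x$plants), n_laterals = sum(nl),
         n_timesteps = x$n_timesteps,
         mean_primary_mm = s$mean[1],
         mean_lateral_total_mm = s$mean[2])
}

#' Generic tidier (broom-style)
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Generic one-row summary (broom-style)
#' @param x object to summarise.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write an elongation heatmap as CSV
#'
#' One row per depth bin, one column per observation interval; empty
#' cells (no lateral in the bin) stay empty, distinct from zero growth.
#'
#' @param hm an [elongation_heatmap()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  utils::write.csv(hm$heatmap, path, na = "")
  invisible(path)
}
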