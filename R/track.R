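#' Tracking configuration
#'
#' Parameters of the crossing-resolution cost function and artefact
#' rejection. The connection cost is the weighted mean of four features in
#' [0, 1]; features that cannot be estimated from enough trajectory
#' support are replaced by the majoring value 1.
#'
#' @param max_connection_cost pairs above this cost are never connected
#'   (mandatory stop criterion of the matching loop).
#' @param feature_weights weights of (virtual edge weight, angle, speed
#'   difference, topological score); the topological score carries the
#'   most weight because it is the only feature that distinguishes local
#'   crossing fragments from unrelated distant chains.
#' @param edge_weight_cap virtual edge weights are rescaled affinely from
#'   `[-1, edge_weight_cap]` to `[0, 1]`.
#' @param topo_norm normalizer of the topological score.
#' @param search_radius maximum hops explored in the original graph for
#'   the topological score; pairs with no undirected path within it are
#'   not plausible reconnections and are inadmissible.
#' @param max_connection_dist_px centroid distance beyond which a pair is
#'   inadmissible.
#' @param min_support_px minimum trajectory extent (px) needed to estimate
#'   a direction.
#' @param speed_window number of trailing/leading regions used for speed
#'   and direction estimates.
#' @param made_factor outlier bound in MADe units for artefact rejection.
#' @param made_epsilon floor of the MADe to avoid zero-spread degeneracy.
#' @param min_population minimum number of lateral roots required to apply
#'   artefact rejection at all.
#' @return a list of class `tracking_config`.
#' @export
tracking_config <- function(max_connection_cost = 0.9,
                            feature_weights = c(0.2, 0.3, 0.15, 0.35),
                            edge_weight_cap = 3, topo_norm = 8,
                            search_radius = 10,
                            max_connection_dist_px = 120,
                            min_support_px = 5,
                            speed_window = 3, made_factor = 25,
                            made_epsilon = 1e-6, min_population = 5) {
  structure(as.list(environment()), class = "tracking_config")
}

#' Mark primary-root paths in a region graph
#'
#' Sources are the `n_plants` largest components carrying the earliest
#' apparition label; from each, the primary path is the maximal greedy
#' walk along minimum-weight outgoing edges. Everything else is labelled
#' lateral; lateral edges pointing into primary vertices are eliminated
#' (root hierarchy), and vertices unreachable from any primary vertex are
#' dropped as outliers.
#'
#' @param G a `region_graph` from [build_rag()].
#' @param n_plants number of seedlings on the plate.
#' @param max_source_row optional image row; when set, source candidates
#'   must have their centroid above it. Seeds are sown on a known line
#'   near the top of the plate, so early dirt or condensation appearing
#'   deeper cannot seat a plant.
#' @return the graph with roles, plant assignments and filtered edges; the
#'   full edge set is kept in `$edges_full`.
#' @export
extract_primaries <- function(G, n_plants, max_source_row = NULL) {
  V <- G$vertices; E <- G$edges
  if (!nrow(V)) stop("empty region graph")
  t_min <- min(V$t)
  cand <- V[V$t == t_min, ]
  if (!is.null(max_source_row)) cand <- cand[cand$cy <= max_source_row, ]
  if (nrow(cand) < n_plants)
    stop(sprintf(paste0("cannot seat %d plants: only %d components carry ",
                        "the earliest label %d"),
                 n_plants, nrow(cand), t_min))
  cand <- cand[order(-cand$npx, cand$id), ]
  sources <- cand$id[seq_len(n_plants)]
  # number plants left to right by seed position
  sources <- sources[order(V$cx[match(sources, V$id)])]
  role <- setNames(rep("lateral", nrow(V)), V$id)
  plant <- setNames(rep(NA_integer_, nrow(V)), V$id)
  E$primary <- FALSE
  for (p in seq_along(sources)) {
    v <- sources[p]
    role[as.character(v)] <- "primary"
    plant[as.character(v)] <- p
    repeat {
      out <- E[E$from == v & role[as.character(E$to)] != "primary", ]
      if (!nrow(out)) break
      out <- out[order(out$w, V$t[match(out$to, V$id)],
                       -V$npx[match(out$to, V$id)], out$to), ]
      nxt <- out$to[1]
      E$primary[E$from == v & E$to == nxt] <- TRUE
      role[as.character(nxt)] <- "primary"
      plant[as.character(nxt)] <- p
      v <- nxt
    }
  }
  V$role <- unname(role)
  V$plant <- unname(plant)
  # hierarchy filter: drop lateral arcs entering a primary vertex and
  # non-path arcs between primary vertices; keep primary -> lateral arcs
  to_primary <- V$role[match(E$to, V$id)] == "primary"
  keep <- E$primary | !to_primary
  E <- E[keep, ]
  # outlier removal: forward reachability from primary vertices
  reach <- V$role == "primary"
  names(reach) <- V$id
  repeat {
    grow <- E$to[reach[as.character(E$from)] & !reach[as.character(E$to)]]
    if (!length(grow)) break
    reach[as.character(grow)] <- TRUE
  }
  dropped <- V$id[!reach]
  if (length(dropped)) {
    V <- V[reach, ]
    E <- E[!(E$from %in% dropped) & !(E$to %in% dropped), ]
  }
  G$vertices <- V
  G$edges <- E
  attr(G, "n_outliers_dropped") <- length(dropped)
  attr(G, "sources") <- sources
  G
}

#' Prune a region graph to a spanning organ forest
#'
#' Computes the minimum-weight directed spanning forest rooted at the
#' primary sources with Edmonds' algorithm (primary-path arcs are forced
#' into the solution), then enforces that lateral roots do not branch by
#' keeping only the minimum-weight outgoing arc of every lateral vertex;
#' severed subtrees become candidate root starts for crossing resolution.
#'
#' @param G a `region_graph` processed by [extract_primaries()].
#' @return an `organ_forest`: list with `graph`, `edges` (tibble of forest
#'   arcs) and the source vertices.
#' @export
prune_to_forest <- function(G) {
  V <- G$vertices; E <- G$edges
  idx <- setNames(seq_len(nrow(V)), V$id)    # vertex id -> 1..n
  n <- nrow(V)
  root <- n + 1L
  sources <- attr(G, "sources")
  force_pen <- 1e6
  ed <- data.frame(from = unname(idx[as.character(E$from)]),
                   to = unname(idx[as.character(E$to)]),
                   w = E$w - ifelse(E$primary, force_pen, 0))
  ed <- rbind(ed, data.frame(from = root,
                             to = unname(idx[as.character(sources)]),
                             w = 0))
  sol <- min_arborescence(n + 1L, ed, root)
  chosen <- sol$edge_idx[sol$edge_idx <= nrow(E)]
  FE <- E[chosen, ]
  # no lateral branching: keep only the min-weight outgoing arc of each
  # lateral vertex (ties: smaller target label, then larger target size)
  lat <- V$id[V$role == "lateral"]
  keep <- rep(TRUE, nrow(FE))
  for (v in intersect(lat, FE$from[duplicated(FE$from)])) {
    rows <- which(FE$from == v)
    ord <- order(FE$w[rows], V$t[match(FE$to[rows], V$id)],
                 -V$npx[match(FE$to[rows], V$id)], FE$to[rows])
    keep[rows[ord[-1]]] <- FALSE
  }
  FE <- FE[keep, ]
  structure(list(graph = G, edges = FE, sources = sources),
            class = "organ_forest")
}

#' @export
print.organ_forest <- function(x, ...) {
  cat(sprintf("<organ_forest> %d vertices, %d arcs, %d plants\n",
              nrow(x$graph$vertices), nrow(x$edges), length(x$sources)))
  invisible(x)
}

#' Root starts and root stops of a forest
#'
#' `V_start` holds every lateral vertex with no incoming arc (roots of
#' detached chains); `V_stop` every vertex with no outgoing arc.
#'
#' @param forest an `organ_forest`.
#' @return list with integer vertex ids `start` and `stop`.
#' @export
forest_endpoints <- function(forest) {
  V <- forest$graph$vertices
  FE <- forest$edges
  start <- V$id[V$role == "lateral" & !(V$id %in% FE$to)]
  stop <- V$id[!(V$id %in% FE$from)]
  list(start = start, stop = stop)
}

# Ordered chain of vertices of the organ containing `v` going backward to
# its chain head, and forward to its chain end, following forest arcs.
chain_upstream <- function(forest, v, n_max = Inf) {
  FE <- forest$edges
  out <- v
  while (length(out) < n_max) {
    up <- FE$from[FE$to == out[1]]
    if (!length(up)) break
    out <- c(up[1], out)
  }
  out
}

chain_downstream <- function(forest, v, n_max = Inf) {
  FE <- forest$edges
  out <- v
  while (length(out) < n_max) {
    dn <- FE$to[FE$from == out[length(out)]]
    if (!length(dn)) break
    out <- c(out, dn[1])
  }
  out
}

trajectory_direction <- function(forest, ids, cfg) {
  # direction along the centroid trajectory of `ids` (ordered base->tip);
  # NULL when the spatial support is too short to be meaningful
  V <- forest$graph$vertices
  i <- match(ids, V$id)
  if (length(i) < 2) return(NULL)
  d <- c(V$cx[i[length(i)]] - V$cx[i[1]], V$cy[i[length(i)]] - V$cy[i[1]])
  len <- sqrt(sum(d^2))
  if (len < cfg$min_support_px) return(NULL)
  d / len
}

trajectory_speed <- function(forest, ids) {
  # centroid path length per observation interval over `ids` (ordered)
  V <- forest$graph$vertices
  i <- match(ids, V$id)
  if (length(i) < 2) return(NULL)
  seg <- sqrt(diff(V$cx[i])^2 + diff(V$cy[i])^2)
  dt <- diff(V$t[i])
  sum(seg) / max(sum(dt), 1)
}

topo_score_path <- function(G, v_from, v_to, max_hops) {
  # minimum-hop undirected path in the original graph, preferring (among
  # shortest paths) the one crossing the fewest arcs backward; returns
  # c(hops, wrong) or NULL when no path within max_hops
  EF <- G$edges_full
  if (is.null(EF) || !nrow(EF)) return(NULL)
  # lexicographic Dijkstra: cost = hops * 1000 + wrong-direction count
  ids <- unique(c(G$vertices$id, EF$from, EF$to))
  dist <- setNames(rep(Inf, length(ids)), ids)
  dist[as.character(v_from)] <- 0
  frontier <- v_from
  adj_f <- split(seq_len(nrow(EF)), EF$from)
  adj_t <- split(seq_len(nrow(EF)), EF$to)
  # simple Bellman-type relaxation bounded by max_hops rounds
  for (h in seq_len(max_hops)) {
    if (!length(frontier)) break
    new_frontier <- integer(0)
    for (v in frontier) {
      dv <- dist[as.character(v)]
      fwd <- adj_f[[as.character(v)]]
      bwd <- adj_t[[as.character(v)]]
      for (e in fwd) {
        u <- EF$to[e]
        nd <- dv + 1000
        if (nd < dist[as.character(u)]) {
          dist[as.character(u)] <- nd
          new_frontier <- c(new_frontier, u)
        }
      }
      for (e in bwd) {
        u <- EF$from[e]
        nd <- dv + 1001                      # against the arc direction
        if (nd < dist[as.character(u)]) {
          dist[as.character(u)] <- nd
          new_frontier <- c(new_frontier, u)
        }
      }
    }
    frontier <- unique(new_frontier)
    if (is.finite(dist[as.character(v_to)]) &&
        dist[as.character(v_to)] < (h + 1) * 1000) break
  }
  d <- unname(dist[as.character(v_to)])
  if (!is.finite(d)) return(NULL)
  c(hops = floor(d / 1000), wrong = d %% 1000)
}

#' Connection cost between a root stop and a root start
#'
#' Weighted mean of four continuity features, each normalized to [0, 1]:
#' the virtual region-adjacency edge weight, the angle between the stop's
#' terminal and the start's initial growth directions, the relative speed
#' difference, and a topological score from the minimum-hop undirected
#' path in the original graph (wrong-direction arcs plus temporal gap).
#' Features lacking sufficient trajectory support take the majoring value
#' 1. Pairs going backward in time are inadmissible (`Inf`).
#'
#' @param v_stop,v_start vertex ids from [forest_endpoints()].
#' @param G the region graph (with `$edges_full`).
#' @param forest the pruned `organ_forest`.
#' @param cfg a [tracking_config()].
#' @return cost in [0, 1], or `Inf` for inadmissible pairs.
#' @export
connection_cost <- function(v_stop, v_start, G, forest,
                            cfg = tracking_config()) {
  V <- G$vertices
  i_stop <- match(v_stop, V$id); i_start <- match(v_start, V$id)
  if (is.na(i_stop) || is.na(i_start)) return(Inf)
  if (V$t[i_start] < V$t[i_stop]) return(Inf)   # backward in time
  dist_c <- sqrt((V$cx[i_start] - V$cx[i_stop])^2 +
                 (V$cy[i_start] - V$cy[i_stop])^2)
  if (dist_c > cfg$max_connection_dist_px) return(Inf)
  # connecting a chain to itself would create a cycle
  up <- chain_upstream(forest, v_stop)
  if (v_start %in% up) return(Inf)
  # f1: virtual edge weight, rescaled from [-1, cap] to [0, 1]
  dt2 <- max(V$t[i_start], V$t[i_stop] + 1)    # same-interval pairs: gap 0
  p_e <- edge_weight(V$npx[i_stop], V$npx[i_start], V$t[i_stop], dt2,
                     c(V$cx[i_stop], V$cy[i_stop]),
                     c(V$cx[i_start], V$cy[i_start]))
  f1 <- clamp((p_e + 1) / (cfg$edge_weight_cap + 1), 0, 1)
  # f2: angle between terminal and initial directions
  tail_ids <- chain_upstream(forest, v_stop, cfg$speed_window + 1)
  head_ids <- chain_downstream(forest, v_start, cfg$speed_window + 1)
  d_stop <- trajectory_direction(forest, tail_ids, cfg)
  d_start <- trajectory_direction(forest, head_ids, cfg)
  f2 <- if (is.null(d_stop) || is.null(d_start)) 1 else
    acos(clamp(sum(d_stop * d_start), -1, 1)) / pi
  # f3: relative speed difference
  s_stop <- trajectory_speed(forest, tail_ids)
  s_start <- trajectory_speed(forest, head_ids)
  f3 <- if (is.null(s_stop) || is.null(s_start)) 1
        else if (s_stop + s_start == 0) 0
        else abs(s_stop - s_start) / (s_stop + s_start)
  # f4: topological score in the original graph -- edges crossed in either
  # direction plus the temporal gap; topologically disconnected pairs are
  # not crossing fragments and are inadmissible
  ts <- topo_score_path(G, v_stop, v_start, cfg$search_radius)
  if (is.null(ts)) return(Inf)
  f4 <- clamp((ts["hops"] + ts["wrong"] +
                 abs(V$t[i_start] - V$t[i_stop] - 1)) /
                cfg$topo_norm, 0, 1)
  sum(cfg$feature_weights * c(f1, f2, f3, unname(f4))) /
    sum(cfg$feature_weights)
}

#' Resolve root crossings by iterated optimal matching
#'
#' Builds the cost matrix of all (root stop, root start) pairs, solves the
#' assignment with the Hungarian algorithm, applies only the matched pair
#' of minimal cost (if below `max_connection_cost`), then updates the
#' forest and repeats until no admissible pair remains. Each applied
#' connection splices a detached chain onto the end of an earlier root,
#' so reconnected roots span their crossings as single organs.
#'
#' @param forest an `organ_forest` from [prune_to_forest()].
#' @param G the region graph (for the original-edge topological score);
#'   defaults to the forest's own graph.
#' @param cfg a [tracking_config()].
#' @return the forest with spliced arcs added (`spliced = TRUE`); the
#'   number of connections applied is in `attr(, "n_connected")`.
#' @export
resolve_crossings <- function(forest, G = forest$graph,
                              cfg = tracking_config()) {
  n_connected <- 0
  repeat {
    ep <- forest_endpoints(forest)
    if (!length(ep$start) || !length(ep$stop)) break
    cost <- matrix(Inf, length(ep$stop), length(ep$start))
    for (i in seq_along(ep$stop))
      for (j in seq_along(ep$start))
        cost[i, j] <- connection_cost(ep$stop[i], ep$start[j], G, forest,
                                      cfg)
    if (!any(is.finite(cost))) break
    sol <- solve_assignment(cost)
    if (!nrow(sol$assignment)) break
    k <- which.min(sol$assignment$cost)
    best <- sol$assignment[k, ]
    if (best$cost > cfg$max_connection_cost) break
    v_stop <- ep$stop[best$row]
    v_start <- ep$start[best$col]
    V <- forest$graph$vertices
    i1 <- match(v_stop, V$id); i2 <- match(v_start, V$id)
    w <- edge_weight(V$npx[i1], V$npx[i2], V$t[i1],
                     max(V$t[i2], V$t[i1] + 1),
                     c(V$cx[i1], V$cy[i1]), c(V$cx[i2], V$cy[i2]))
    forest$edges <- dplyr::bind_rows(
      forest$edges,
      tibble(from = v_stop, to = v_start, w = w, primary = FALSE,
             spliced = TRUE))
    n_connected <- n_connected + 1
  }
  attr(forest, "n_connected") <- n_connected
  forest
}

#' Robust MADe outlier flags
#'
#' Flags values outside `median +/- factor * MADe`, with
#' `MADe = 1.483 * median(|x - median(x)|)` floored at `eps`.
#'
#' @param x numeric values.
#' @param factor bound in MADe units (default 25).
#' @param eps floor on the MADe.
#' @return logical vector, `TRUE` for outliers.
#' @export
made_outliers <- function(x, factor = 25, eps = 1e-6) {
  med <- median(x)
  made <- max(1.483 * median(abs(x - med)), eps)
  abs(x - med) > factor * made
}

#' Reject artefact roots by robust per-age statistics
#'
#' For every lateral root, three scalar series are measured at each
#' timestep and binned by the temporal distance from the root's emergence:
#' cumulative centroid-path length, speed (centroid displacement per
#' interval) and cumulative surface (pixels). Within each age bin, roots
#' whose value deviates from the bin median by more than
#' `made_factor * MADe` in any statistic are removed as artefacts. Skipped
#' entirely when fewer than `min_population` laterals exist.
#'
#' @param forest a resolved `organ_forest`.
#' @param cfg a [tracking_config()].
#' @return the forest with artefact chains removed; rejected organ head
#'   ids in `attr(, "rejected")`.
#' @export
reject_artefact_roots <- function(forest, cfg = tracking_config()) {
  organs <- forest_organ_chains(forest)
  lat <- organs[vapply(organs, function(o) o$order == 2, logical(1))]
  attr(forest, "rejected") <- integer(0)
  if (length(lat) < cfg$min_population) return(forest)
  V <- forest$graph$vertices
  stats_list <- lapply(lat, function(o) {
    i <- match(o$chain, V$id)
    seg <- if (length(i) > 1)
      sqrt(diff(V$cx[i])^2 + diff(V$cy[i])^2) else numeric(0)
    tibble(age = seq_along(i),
           length = c(0, cumsum(seg)),
           speed = c(0, seg / pmax(diff(V$t[i]), 1)),
           surface = cumsum(V$npx[i]))
  })
  n_ages <- max(vapply(stats_list, nrow, integer(1)))
  bad <- rep(FALSE, length(lat))
  for (a in seq_len(n_ages)) {
    have <- which(vapply(stats_list, nrow, integer(1)) >= a)
    if (length(have) < cfg$min_population) next
    for (stat in c("length", "speed", "surface")) {
      vals <- vapply(have, function(k) stats_list[[k]][[stat]][a],
                     numeric(1))
      out <- made_outliers(vals, cfg$made_factor, cfg$made_epsilon)
      bad[have[out]] <- TRUE
    }
  }
  if (any(bad)) {
    drop_ids <- unlist(lapply(lat[bad], `[[`, "chain"))
    forest$edges <- forest$edges[!(forest$edges$from %in% drop_ids |
                                     forest$edges$to %in% drop_ids), ]
    attr(forest, "rejected") <-
      vapply(lat[bad], function(o) o$chain[1], integer(1))
  }
  forest
}

#' Ordered organ chains of a forest
#'
#' Follows forest arcs to enumerate organs: one primary chain per plant
#' (continuing through spliced arcs at primary stops) and one chain per
#' lateral root (starting at lateral vertices attached to a primary vertex
#' by a regular arc, or detached chain heads). Unattached chains are
#' flagged.
#'
#' @param forest an `organ_forest`.
#' @return list of entries `list(chain, order, plant, attached_to,
#'   attached)`; `chain` is the ordered vertex-id vector.
#' @export
forest_organ_chains <- function(forest) {
  V <- forest$graph$vertices
  FE <- forest$edges
  role <- setNames(V$role, V$id)
  out <- list()
  consumed <- character(0)
  # primaries
  for (p in seq_along(forest$sources)) {
    chain <- forest$sources[p]
    repeat {
      nxt <- FE[FE$from == chain[length(chain)], ]
      nxt_primary <- nxt[role[as.character(nxt$to)] == "primary", ]
      if (nrow(nxt_primary)) { chain <- c(chain, nxt_primary$to[1]); next }
      nxt_splice <- nxt[nxt$spliced, ]
      if (nrow(nxt_splice) == 1 && !nrow(nxt_primary) &&
          nrow(nxt) == nrow(nxt_splice)) {
        # splice at a primary stop continues the primary organ
        chain <- c(chain, nxt_splice$to[1]); next
      }
      break
    }
    out[[length(out) + 1]] <- list(chain = chain, order = 1L, plant = p,
                                   attached_to = NA_integer_,
                                   attached = TRUE)
    consumed <- c(consumed, as.character(chain))
  }
  # laterals: heads are lateral vertices whose incoming arc comes from a
  # primary vertex (regular emergence) -- except vertices already used as
  # primary continuations -- plus detached heads
  lat_ids <- V$id[V$role == "lateral"]
  lat_ids <- setdiff(lat_ids, as.integer(consumed))
  incoming <- FE[match(lat_ids, FE$to), ]
  is_head <- is.na(incoming$from) |
    (role[as.character(incoming$from)] == "primary")
  heads <- lat_ids[is_head]
  for (h in heads) {
    chain <- h
    repeat {
      nxt <- FE$to[FE$from == chain[length(chain)]]
      nxt <- setdiff(nxt, as.integer(consumed))
      if (!length(nxt)) break
      chain <- c(chain, nxt[1])
    }
    parent <- FE$from[FE$to == h]
    attached <- length(parent) > 0
    plant <- if (attached) V$plant[match(parent[1], V$id)] else NA_integer_
    out[[length(out) + 1]] <- list(chain = chain, order = 2L,
                                   plant = plant,
                                   attached_to = if (attached) parent[1]
                                                 else NA_integer_,
                                   attached = attached)
    consumed <- c(consumed, as.character(chain))
  }
  out
}

#' Dump a region graph or forest to JSON lines
#'
#' One JSON object per line: first the vertices, then the edges. Pixel
#' sets are not serialized.
#'
#' @param G a `region_graph` or `organ_forest`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graph_jsonl <- function(G, path) {
  if (inherits(G, "organ_forest")) {
    edges <- G$edges; V <- G$graph$vertices
  } else {
    edges <- G$edges; V <- G$vertices
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(V)))
    writeLines(jsonlite::toJSON(c(kind = "vertex",
                                  as.list(V[i, ])), auto_unbox = TRUE,
                                digits = NA), con)
  for (i in seq_len(nrow(edges)))
    writeLines(jsonlite::toJSON(c(kind = "edge",
                                  as.list(edges[i, ])), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}
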