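#' Minimum spanning arborescence (Chu-Liu/Edmonds)
#'
#' Finds the minimum-weight set of arcs such that every vertex except
#' `root` has exactly one incoming arc and all vertices are reachable from
#' `root`. Implemented by the classical cycle-contraction scheme; weights
#' may be negative. Ties are broken by first occurrence in `edges`, so the
#' result is deterministic.
#'
#' @param n_vertices number of vertices, labelled `1..n_vertices`.
#' @param edges matrix or data frame with columns `from`, `to`, `w`.
#' @param root root vertex index.
#' @return list with `edge_idx` (row indices into `edges` of the chosen
#'   arcs) and `weight` (their total weight).
#' @export
min_arborescence <- function(n_vertices, edges, root) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "w") %in% names(edges)))
  if (n_vertices == 1) return(list(edge_idx = integer(0), weight = 0))
  sol <- edmonds_rec(setdiff(seq_len(n_vertices), root),
                     edges$from, edges$to, edges$w,
                     seq_len(nrow(edges)), root)
  list(edge_idx = sort(sol), weight = sum(edges$w[sol]))
}

edmonds_rec <- function(active, from, to, w, ids, root) {
  # `active`: vertices (other than root) still to be covered at this level.
  # Returns values drawn from `ids` (the caller's labels for the arcs).
  maxv <- max(c(active, root, from, to))
  best <- rep(NA_integer_, maxv)    # local arc index of min incoming arc
  is_active <- logical(maxv); is_active[active] <- TRUE
  for (e in seq_along(from)) {
    v <- to[e]
    if (!is_active[v] || from[e] == v) next
    if (is.na(best[v]) || w[e] < w[best[v]]) best[v] <- e
  }
  unreach <- active[is.na(best[active])]
  if (length(unreach))
    stop("vertices unreachable from the root: ",
         paste(unreach, collapse = ", "))
  # follow v -> from[best[v]] to find a cycle among chosen arcs
  cyc <- NULL
  color <- integer(maxv)            # 0 unseen, 1 in progress, 2 done
  for (s in active) {
    if (color[s] != 0) next
    path <- integer(0); v <- s
    repeat {
      if (v == root || !is_active[v] || color[v] == 2) break
      if (color[v] == 1) {
        cyc <- path[match(v, path):length(path)]
        break
      }
      color[v] <- 1
      path <- c(path, v)
      v <- from[best[v]]
    }
    color[path] <- 2
    if (!is.null(cyc)) break
  }
  if (is.null(cyc)) return(ids[best[active]])
  # contract the cycle into a fresh super vertex
  super <- maxv + 1L
  incyc <- logical(maxv); incyc[cyc] <- TRUE
  keep <- logical(length(from))
  nf <- from; nt <- to; nw <- w
  for (e in seq_along(from)) {
    u <- from[e]; v <- to[e]
    inu <- u <= maxv && incyc[u]; inv <- v <= maxv && incyc[v]
    if (inu && inv) next
    keep[e] <- TRUE
    if (inv) { nw[e] <- w[e] - w[best[v]]; nt[e] <- super }
    if (inu) nf[e] <- super
  }
  sub <- which(keep)
  active2 <- c(setdiff(active, cyc), super)
  chosen <- edmonds_rec(active2, nf[sub], nt[sub], nw[sub], sub, root)
  # `chosen` are local arc indices at this level; exactly one of them
  # enters the contracted cycle -- reopen the cycle at its original head
  entering <- chosen[incyc[pmin(to[chosen], maxv)] & to[chosen] <= maxv]
  stopifnot(length(entering) == 1)
  v_in <- to[entering]
  cycle_arcs <- best[setdiff(cyc, v_in)]
  ids[c(chosen, cycle_arcs)]
}
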