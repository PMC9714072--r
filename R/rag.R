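#' Weighted directed region adjacency graph of an apparition-time image
#'
#' Vertices are the 8-connected components of equal-label pixels of `S`;
#' two vertices are joined by a directed edge when their components are
#' 4-neighbours (share at least a pixel edge), directed forward in time
#' (`t(v1) < t(v2)`), and weighted by [edge_weight()]. The graph is acyclic
#' by construction.
#'
#' @param S a filtered [apparition_image()].
#' @return a `region_graph`: list with `vertices` (tibble: id, t, npx, cx,
#'   cy, role, plant), `edges` (tibble: from, to, w, primary, spliced),
#'   `edges_full` (all edges, kept for topological scoring after
#'   filtering), `pixels` (list of linear pixel indices per vertex),
#'   `vid` (vertex-id image) and the acquisition geometry.
#' @export
build_rag <- function(S) {
  nr <- nrow(S); nc <- ncol(S)
  smat <- matrix(as.integer(S), nr, nc)
  vid <- cc_label_cpp(smat, 8L)
  n_v <- max(vid)
  if (n_v == 0) {
    g <- list(vertices = tibble(id = integer(), t = integer(),
                                npx = integer(), cx = numeric(),
                                cy = numeric(), role = character(),
                                plant = integer()),
              edges = tibble(from = integer(), to = integer(),
                             w = numeric(), primary = logical(),
                             spliced = logical()),
              edges_full = NULL, pixels = list(), vid = vid,
              shape = c(nr, nc), n_timesteps = attr(S, "n_timesteps"),
              px_size_um = attr(S, "px_size_um"),
              timestep_h = attr(S, "timestep_h"))
    class(g) <- "region_graph"
    return(g)
  }
  idx <- which(vid > 0)
  v <- vid[idx]
  npx <- tabulate(v, n_v)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  cy <- rowsum(rows, v)[, 1] / npx
  cx <- rowsum(cols, v)[, 1] / npx
  lab <- integer(n_v)
  lab[v] <- smat[idx]
  pixels <- split(idx, v)
  vertices <- tibble(id = seq_len(n_v), t = lab, npx = npx,
                     cx = cx, cy = cy,
                     role = rep("unassigned", n_v),
                     plant = rep(NA_integer_, n_v))
  pairs <- adjacency_pairs_cpp(vid)
  if (nrow(pairs) > 0) {
    t1 <- lab[pairs[, 1]]; t2 <- lab[pairs[, 2]]
    # same-label components cannot be 4-adjacent (they would be one
    # 8-connected component); direct each pair forward in time
    from <- ifelse(t1 < t2, pairs[, 1], pairs[, 2])
    to <- ifelse(t1 < t2, pairs[, 2], pairs[, 1])
    w <- edge_weight(npx[from], npx[to], lab[from], lab[to],
                     cbind(cx[from], cy[from]), cbind(cx[to], cy[to]))
    edges <- tibble(from = from, to = to, w = w,
                    primary = FALSE, spliced = FALSE)
    edges <- edges[order(edges$from, edges$to), ]
  } else {
    edges <- tibble(from = integer(), to = integer(), w = numeric(),
                    primary = logical(), spliced = logical())
  }
  g <- list(vertices = vertices, edges = edges, edges_full = edges,
            pixels = pixels, vid = vid, shape = c(nr, nc),
            n_timesteps = attr(S, "n_timesteps"),
            px_size_um = attr(S, "px_size_um"),
            timestep_h = attr(S, "timestep_h"))
  class(g) <- "region_graph"
  g
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %d vertices, %d edges, labels %s..%s\n",
              nrow(x$vertices), nrow(x$edges),
              if (nrow(x$vertices)) min(x$vertices$t) else "-",
              if (nrow(x$vertices)) max(x$vertices$t) else "-"))
  invisible(x)
}

#' Edge weight of the region adjacency graph
#'
#' `p(e) = |#v1 - #v2| / (#v1 + #v2) + (t(v2) - t(v1) - 1) + u . y` where
#' `u` is the unit vector from v1's centroid to v2's centroid and `y` the
#' upward unit vector (opposite to gravity, toward decreasing row index):
#' an edge is cheap when the regions have comparable surface, consecutive
#' labels, and the target lies straight below the source (third term -1).
#'
#' @param n1,n2 pixel counts of the two components.
#' @param t1,t2 labels (apparition times), `t1 < t2`.
#' @param c1,c2 centroids, `c(x, y)` or two-column matrices (x, y).
#' @return numeric edge weight(s).
#' @export
edge_weight <- function(n1, n2, t1, t2, c1, c2) {
  if (!is.matrix(c1)) c1 <- matrix(c1, ncol = 2)
  if (!is.matrix(c2)) c2 <- matrix(c2, ncol = 2)
  dx <- c2[, 1] - c1[, 1]
  dy <- c2[, 2] - c1[, 2]
  len <- sqrt(dx^2 + dy^2)
  vert <- ifelse(len > 0, -dy / len, 0)  # u . y_up, y_up = (0, -1)
  abs(n1 - n2) / (n1 + n2) + (t2 - t1 - 1) + vert
}
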