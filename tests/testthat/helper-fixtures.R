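# Shared fixtures: small synthetic worlds and constructed label images.

# tiny plate: 1-2 plants at very coarse resolution, fast to simulate
tiny_params <- function(n_plants = 2, seed = 7, ...) {
  defaults <- list(n_plants = n_plants, px_size_um = 150, noise_sd = 0,
                   jitter = c(0, 0), artifact_rate = 0, crossing_bias = 0,
                   lateral_density = 0.1, seed = seed)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# apparition image from an integer matrix (labels), default geometry
label_image <- function(m, n_t = max(m), px = 150) {
  apparition_image(matrix(as.integer(m), nrow(m), ncol(m)), n_t, px, 8)
}

# textured test image: smoothed random field, reproducible
textured_image <- function(nr, nc, seed = 1, sd = 40, mean = 150) {
  set.seed(seed)
  x <- matrix(rnorm(nr * nc), nr, nc)
  k <- 7
  x <- t(apply(x, 1, function(r) stats::filter(r, rep(1 / k, k),
                                               circular = TRUE)))
  x <- apply(x, 2, function(r) stats::filter(r, rep(1 / k, k),
                                             circular = TRUE))
  mean + sd * (x - mean(x)) / sd(x)
}

# brute-force minimum spanning arborescence by enumerating all choices of
# one incoming arc per non-root vertex and checking reachability
brute_arborescence <- function(n, edges, root) {
  edges <- as.data.frame(edges)
  choices <- lapply(seq_len(n), function(v) {
    if (v == root) return(0L)
    which(edges$to == v & edges$from != v)
  })
  if (any(vapply(choices, length, integer(1)) == 0 &
          seq_len(n) != root)) return(NULL)
  grid <- expand.grid(choices[-root], KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    sel <- as.integer(grid[i, ])
    parent <- integer(n)
    for (k in seq_along(sel)) parent[edges$to[sel[k]]] <- edges$from[sel[k]]
    # reachability from root through chosen arcs
    ok <- TRUE
    for (v in seq_len(n)) {
      if (v == root) next
      seen <- logical(n); cur <- v
      while (cur != root) {
        if (seen[cur] || parent[cur] == 0) { ok <- FALSE; break }
        seen[cur] <- TRUE
        cur <- parent[cur]
      }
      if (!ok) break
    }
    if (ok) best <- min(best, sum(edges$w[sel]))
  }
  if (is.finite(best)) best else NULL
}

# brute-force assignment by enumerating all permutations
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  if (n <= m) {
    perms <- combinat_permn(seq_len(m))
    best <- Inf
    for (p in perms) best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
  } else {
    perms <- combinat_permn(seq_len(n))
    best <- Inf
    for (p in perms) best <- min(best, sum(cost[cbind(p[seq_len(m)], seq_len(m))]))
  }
  best
}

combinat_permn <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_permn(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
  out
}

# random digraph generator for oracle comparisons
random_digraph <- function(n, p_edge = 0.45, dag = FALSE, seed = 1) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (dag && a >= b) next
    if (runif(1) < p_edge) { from <- c(from, a); to <- c(to, b) }
  }
  data.frame(from = from, to = to,
             w = round(runif(length(from), -2, 5), 3))
}
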