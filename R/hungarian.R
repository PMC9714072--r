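#' Optimal assignment (Hungarian algorithm)
#'
#' Minimum-cost one-to-one assignment of rows to columns by the
#' Jonker-Volgenant shortest-augmenting-path formulation (O(n^3)).
#' Rectangular matrices are handled by assigning `min(n, m)` pairs;
#' non-finite costs mark inadmissible pairs and are never chosen unless no
#' finite-cost perfect matching exists for a row.
#'
#' @param cost numeric cost matrix (rows x columns).
#' @return list with `assignment` (tibble: row, col, cost, one row per
#'   matched pair, inadmissible matches dropped) and `total` (their summed
#'   cost).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0)
    return(list(assignment = tibble(row = integer(), col = integer(),
                                    cost = numeric()), total = 0))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; n <- nrow(cost); m <- ncol(cost) }
  big <- max(cost[is.finite(cost)], 0) * (n + m + 1) + 1
  a <- cost
  a[!is.finite(a)] <- big
  # Jonker-Volgenant with a virtual column 0 (index 1 in the arrays)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)               # p[j+1]: row assigned to column j
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- a[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  rows <- p[-1]
  ok <- rows > 0
  res <- tibble(row = rows[ok], col = which(ok))
  res$cost <- cost[cbind(res$row, res$col)]
  if (transposed) res <- tibble(row = res$col, col = res$row,
                                cost = res$cost)
  res <- res[is.finite(res$cost), ]
  res <- res[order(res$row), ]
  list(assignment = res, total = sum(res$cost))
}
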