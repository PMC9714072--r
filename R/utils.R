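`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Polyline arc length
#' @param xy two-column matrix of coordinates.
#' @return total euclidean length.
#' @keywords internal
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

# Cumulative arc length at each node (starts at 0).
polyline_cumlen <- function(xy) {
  if (nrow(xy) < 2) return(0)
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

# Deterministic seed derivation: keeps values well under 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 13L
}
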