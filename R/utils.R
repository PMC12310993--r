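# Internal helpers shared across modules.

# Euclidean norms of the rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Pairwise Euclidean distances between the rows of a (n x 3) and b (m x 3);
# returns an n x m matrix. Computed stably without forming cross terms so
# mirror-symmetric inputs give bitwise-symmetric outputs.
cross_dist <- function(a, b) {
  n <- nrow(a)
  m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in seq_len(ncol(a))) {
    out <- out + outer(a[, k], b[, k], function(x, y) (x - y)^2)
  }
  sqrt(out)
}

# Polyline arclengths: distances between consecutive rows of a point matrix.
interval_lengths <- function(pos) {
  d <- diff(pos)
  sqrt(rowSums(d * d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_perfterra <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "perfterra_error")))
}
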