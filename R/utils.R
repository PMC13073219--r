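# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Euclidean distances from one point to many points (km).
dist_to <- function(x, y, xs, ys) {
  sqrt((xs - x)^2 + (ys - y)^2)
}

# Nearest node (row index into nodes) for each query point; plain loop over
# query points keeps memory flat for large node sets.
nearest_node_index <- function(x, y, nodes) {
  n <- length(x)
  idx <- integer(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    dd <- dist_to(x[i], y[i], nodes$x_km, nodes$y_km)
    j <- which.min(dd)
    idx[i] <- j
    d[i] <- dd[j]
  }
  list(index = idx, distance_km = d)
}

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
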