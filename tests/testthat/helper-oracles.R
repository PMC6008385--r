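# Brute-force reference implementations, independent of the package's
# BFS/Brandes code paths: Floyd-Warshall distances and combinatorial
# shortest-path counting.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# sigma[s, t] = number of shortest s-t paths, from the distance matrix
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(A[, t] == 1 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_path_counts(A, D)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == i || t == i || !is.finite(D[s, t])) next
      if (is.finite(D[s, i]) && is.finite(D[i, t]) &&
          D[s, i] + D[i, t] == D[s, t])
        b[i] <- b[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
    }
  }
  b
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    ci[i] <- sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
  }
  ci
}

oracle_global_eff <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_lp_harmonic <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n * (n - 1) / sum(inv)
}

oracle_local_eff <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(A[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

oracle_nodal_eff <- function(A) {
  D <- oracle_distances(A)
  n <- nrow(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

is_connected <- function(A) all(is.finite(oracle_distances(A)))

# all labeled graphs on n nodes via bitmask over the n(n-1)/2 pairs
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (bits in seq_len(2^m) - 1L) {
    A <- matrix(0L, n, n)
    on <- which(bitwAnd(bits, 2L^(seq_len(m) - 1L)) > 0)
    if (length(on) == 0) next
    A[pairs[on, , drop = FALSE]] <- 1L
    A <- A + t(A)
    if (is_connected(A)) out[[length(out) + 1]] <- A
  }
  out
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up[runif(length(up)) < p]] <- 1L
  A + t(A)
}

# graphs used repeatedly in fixtures
star4 <- function() generate_benchmark_graph("star", 4)
complete4 <- function() generate_benchmark_graph("complete", 4)
tri_pendant <- function() {
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 1L; A[1, 3] <- A[3, 1] <- 1L
  A[2, 3] <- A[3, 2] <- 1L; A[1, 4] <- A[4, 1] <- 1L
  A
}
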