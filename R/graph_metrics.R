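#' Sparsity grid used for network thresholding
#'
#' Default analysis grid: sparsity 0.05 to 0.50 in steps of 0.01
#' (46 levels). Sparsity is the fraction of retained edges relative to
#' the maximum possible `N(N-1)/2`, so thresholding at fixed sparsity
#' equalizes edge counts across subjects.
#'
#' @param lo,hi,step grid bounds and spacing.
#' @return Numeric vector of sparsity levels.
#' @export
sparsity_grid <- function(lo = 0.05, hi = 0.50, step = 0.01) {
  stopifnot(lo > 0, hi <= 1, step > 0, lo < hi)
  round(seq(lo, hi, by = step), 10)
}

round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a target sparsity
#'
#' Keeps the `K = round(Sp * N(N-1)/2)` strongest edges (rounding half
#' away from zero) and sets them to 1. By default edges are ranked by
#' signed correlation (largest r first); `rank = "abs"` ranks by
#' magnitude instead. Ties are broken by lexicographic node-pair order
#' so the result is deterministic.
#'
#' @param C symmetric numeric connectivity matrix (diagonal ignored).
#' @param sp target sparsity in (0, 1].
#' @param rank `"signed"` (default) or `"abs"` edge ranking.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and
#'   attribute `"sparsity"` holding the requested level.
#' @export
binarize_at_sparsity <- function(C, sp, rank = c("signed", "abs")) {
  rank <- match.arg(rank)
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (!(sp > 0 && sp <= 1)) stop("sparsity must be in (0, 1]")
  n <- nrow(C)
  n_pairs <- n * (n - 1) / 2
  k <- round_half_up(sp * n_pairs)
  if (k < 1) stop("sparsity ", sp, " yields zero edges for n = ", n)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[iu]
  key <- if (rank == "abs") abs(vals) else vals
  ord <- order(-key, iu[, 1], iu[, 2])
  keep <- iu[ord[seq_len(k)], , drop = FALSE]
  A <- matrix(0L, n, n, dimnames = dimnames(C))
  A[keep] <- 1L
  A[cbind(keep[, 2], keep[, 1])] <- 1L
  attr(A, "sparsity") <- sp
  A
}

check_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  A
}

#' Local and mean clustering coefficient
#'
#' `Ci` is the fraction of realized connections among node i's
#' neighbors, `2 * t_i / (k_i (k_i - 1))`; nodes with degree < 2 get 0.
#' `Cp` is the mean of `Ci` over all nodes (network segregation).
#'
#' @param A binary adjacency matrix.
#' @return List with `ci` (per-node) and `cp` (network mean).
#' @export
clustering_coefficient <- function(A) {
  A <- check_adjacency(A)
  ci <- cpp_clustering(A)
  names(ci) <- rownames(A)
  list(ci = ci, cp = mean(ci))
}

#' Harmonic-mean characteristic path length
#'
#' `Lp = n(n-1) / sum_{i != j} 1/d_ij` with `1/Inf = 0`, so disconnected
#' graphs still yield a finite value. Satisfies `Lp * Eglob = 1`
#' whenever at least one pair is connected.
#'
#' @param A binary adjacency matrix with at least one edge.
#' @return Scalar path length (>= 1).
#' @export
path_length_harmonic <- function(A) {
  A <- check_adjacency(A)
  s <- cpp_inv_dist_sum(A)
  if (s <= 0) stop("no finite distances: graph has no edges")
  n <- nrow(A)
  n * (n - 1) / s
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over all ordered node pairs;
#' 1 for a complete graph, 0 for an empty one.
#'
#' @param A binary adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  if (n < 2) return(0)
  cpp_inv_dist_sum(A) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced
#' by each node's neighbors; neighbor sets with fewer than 2 nodes
#' contribute 0.
#'
#' @param A binary adjacency matrix.
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(A) {
  A <- check_adjacency(A)
  cpp_local_efficiency(A)
}

#' Nodal centrality metrics
#'
#' Per node: degree (row sum), betweenness (unnormalized Brandes sum of
#' shortest-path fractions over unordered pairs), and nodal efficiency
#' (mean inverse distance to all other nodes).
#'
#' @param A binary adjacency matrix.
#' @return `data.frame` with columns `node`, `degree`, `betweenness`,
#'   `efficiency`.
#' @export
nodal_metrics <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  D <- cpp_bfs_distances(A)
  inv <- ifelse(D > 0, 1 / D, 0)
  data.frame(
    node = if (is.null(rownames(A))) paste0("n", seq_len(n)) else rownames(A),
    degree = as.integer(rowSums(A)),
    betweenness = cpp_betweenness(A),
    efficiency = rowSums(inv) / (n - 1),
    stringsAsFactors = FALSE
  )
}

#' Size of the largest connected component
#'
#' Isolated nodes count as size-1 components; an empty graph therefore
#' has largest component size 1.
#'
#' @param A binary adjacency matrix.
#' @return Integer node count.
#' @export
largest_component_size <- function(A) {
  A <- check_adjacency(A)
  D <- cpp_bfs_distances(A)
  max(rowSums(D >= 0))
}

#' Degree-preserving random rewiring
#'
#' Maslov-Sneppen double-edge swaps: repeatedly pick two edges and swap
#' their endpoints, rejecting candidates that would create self-loops or
#' duplicate edges. The degree sequence (hence edge count) is exactly
#' preserved while topology is randomized.
#'
#' @param A binary adjacency matrix with >= 2 edges.
#' @param swaps_per_edge number of candidate swaps drawn per edge.
#' @param seed optional integer seed; the function is then a pure
#'   function of its inputs.
#' @return Rewired adjacency matrix of the same dimensions.
#' @export
rewire_preserving_degree <- function(A, swaps_per_edge = 100, seed = NULL) {
  A <- check_adjacency(A)
  m <- sum(A) / 2
  if (m < 2) stop("rewiring requires at least 2 edges")
  attempts <- as.integer(round(swaps_per_edge * m))
  with_seed(seed, {
    B <- cpp_rewire(A, attempts)
  })
}

#' Small-world parameters against a degree-preserving null
#'
#' Generates `n_random` degree-matched rewired networks, takes the
#' ensemble means of their clustering coefficient and harmonic path
#' length, and reports `gamma = Cp/Cp_rand`, `lambda = Lp/Lp_rand`, and
#' small-worldness `sigma = gamma/lambda`. A network is called
#' small-world when `gamma > 1`, `lambda ~ 1`, `sigma > 1`.
#'
#' @param A binary adjacency matrix with at least one edge.
#' @param n_random ensemble size (1000 in the reference analysis).
#' @param swaps_per_edge candidate swaps per edge for each rewiring.
#' @param seed optional integer seed for the ensemble.
#' @return List with `gamma`, `lambda`, `sigma`, `cp`, `lp`, `cp_rand`,
#'   `lp_rand`.
#' @export
small_world_parameters <- function(A, n_random = 1000, swaps_per_edge = 100,
                                   seed = NULL) {
  A <- check_adjacency(A)
  stopifnot(n_random >= 1)
  m <- sum(A) / 2
  if (m < 1) stop("graph has no edges")
  cp <- clustering_coefficient(A)$cp
  lp <- path_length_harmonic(A)
  attempts <- as.integer(round(swaps_per_edge * m))
  ens <- with_seed(seed, cpp_smallworld_ensemble(A, as.integer(n_random), attempts))
  cp_rand <- mean(ens[, 1])
  lp_rand <- mean(ens[, 2], na.rm = TRUE)
  if (cp_rand <= 0) {
    warning("null ensemble has zero clustering; gamma/sigma undefined")
    gamma <- NA_real_
  } else {
    gamma <- cp / cp_rand
  }
  lambda <- lp / lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = cp, lp = lp, cp_rand = cp_rand, lp_rand = lp_rand)
}

#' Metric curves across the sparsity grid
#'
#' Thresholds a connectivity matrix at every sparsity level and computes
#' all global metrics (Cp, Lp, gamma, lambda, sigma, Eglob, Eloc,
#' largest component size) and nodal metrics (degree, betweenness,
#' nodal efficiency, clustering) at each level. Per-level failures are
#' propagated as `NA` with a warning rather than aborting the curve.
#'
#' @param C connectivity matrix.
#' @param grid strictly increasing sparsity levels in (0, 1].
#' @param n_random null-ensemble size per level; 0 skips the
#'   small-world normalization (gamma/lambda/sigma become `NA`).
#' @param swaps_per_edge rewiring effort per null network.
#' @param seed integer seed; per-level ensemble seeds are derived
#'   deterministically from it.
#' @param rank edge-ranking mode passed to [binarize_at_sparsity()].
#' @param nodal compute per-node metrics as well (disable for
#'   global-only runs at scale).
#' @return List with `global` and `nodal` long-format data frames, the
#'   `grid`, and matrix forms of the same curves (`global_mat`,
#'   `nodal_mats`, `grid_used`) that [auc_summary()] uses as a fast
#'   path.
#' @export
metric_curves <- function(C, grid = sparsity_grid(), n_random = 1000,
                          swaps_per_edge = 100, seed = NULL,
                          rank = c("signed", "abs"), nodal = TRUE) {
  rank <- match.arg(rank)
  stopifnot(all(diff(grid) > 0), all(grid > 0), all(grid <= 1))
  n <- nrow(C)
  labels <- rownames(C) %||% paste0("n", seq_len(n))
  n_pairs <- n * (n - 1) / 2
  ks <- round_half_up(grid * n_pairs)
  usable <- ks >= 1
  if (any(!usable))
    warning(sum(!usable), " sparsity level(s) yield zero edges; reported as NA")
  # rank all pairs once: strongest first, ties lexicographic
  iu <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[iu]
  key <- if (rank == "abs") abs(vals) else vals
  ord <- order(-key, iu[, 1], iu[, 2])
  eu <- iu[ord, 1] - 1L
  ev <- iu[ord, 2] - 1L

  res <- with_seed(seed,
    cpp_metric_curves(eu, ev, n, as.integer(ks[usable]),
                      as.integer(n_random), swaps_per_edge, nodal))
  g <- res$global
  glob_metrics <- c("cp", "lp", "gamma", "lambda", "sigma",
                    "eglob", "eloc", "largest_component")
  glob <- matrix(NA_real_, length(grid), length(glob_metrics),
                 dimnames = list(NULL, glob_metrics))
  glob[usable, c("cp", "lp", "eglob", "eloc", "largest_component")] <-
    g[, c("cp", "lp", "eglob", "eloc", "largest_component")]
  if (n_random > 0) {
    gamma <- ifelse(g[, "cp_rand"] > 0, g[, "cp"] / g[, "cp_rand"], NA_real_)
    if (any(g[, "cp_rand"] <= 0, na.rm = TRUE))
      warning("null ensemble with zero clustering at some level(s); gamma reported as NA")
    lambda <- g[, "lp"] / g[, "lp_rand"]
    glob[usable, "gamma"] <- gamma
    glob[usable, "lambda"] <- lambda
    glob[usable, "sigma"] <- gamma / lambda
  }
  global_df <- data.frame(
    sparsity = rep(grid, times = length(glob_metrics)),
    metric = rep(glob_metrics, each = length(grid)),
    value = as.vector(glob),
    stringsAsFactors = FALSE
  )
  nodal_df <- NULL
  nodal_mats <- NULL
  if (nodal) {
    nlev <- sum(usable)
    nodal_df <- data.frame(
      node = rep(labels, each = nlev),
      degree = as.vector(res$degree),
      betweenness = as.vector(res$betweenness),
      efficiency = as.vector(res$efficiency),
      clustering = as.vector(res$clustering),
      sparsity = rep(grid[usable], times = n),
      stringsAsFactors = FALSE
    )
    nodal_mats <- lapply(res[c("degree", "betweenness", "efficiency",
                               "clustering")], function(m) {
      colnames(m) <- labels
      m
    })
  }
  list(global = global_df, nodal = nodal_df, grid = grid,
       global_mat = glob, nodal_mats = nodal_mats,
       grid_used = grid[usable])
}

#' Trapezoidal area under a metric curve
#'
#' Threshold-free summary of a metric across the sparsity grid. The AUC
#' of a constant curve `c` equals `c * (grid span)`; the trapezoid rule
#' is exact for linear curves. Missing values are dropped pairwise with
#' a warning.
#'
#' @param values metric values, same length as `grid`.
#' @param grid sparsity levels.
#' @return Scalar integral.
#' @export
metric_auc <- function(values, grid) {
  stopifnot(length(values) == length(grid), length(grid) >= 2)
  ok <- is.finite(values) & is.finite(grid)
  if (any(!ok)) {
    warning(sum(!ok), " non-finite curve point(s) excluded from AUC")
    values <- values[ok]
    grid <- grid[ok]
  }
  if (length(values) < 2) stop("fewer than 2 finite points; AUC undefined")
  sum(diff(grid) * (head(values, -1) + tail(values, -1)) / 2)
}

#' AUC summaries of a set of metric curves
#'
#' @param curves result of [metric_curves()].
#' @return List with `global` (`metric`, `auc`) and `nodal`
#'   (`node`, `metric`, `auc`) data frames.
#' @export
auc_summary <- function(curves) {
  if (!is.null(curves$global_mat)) {
    # matrix fast path (the long data frames carry the same values)
    gm <- curves$global_mat
    global <- data.frame(
      metric = colnames(gm),
      auc = vapply(seq_len(ncol(gm)),
                   function(j) safe_auc(gm[, j], curves$grid), numeric(1)),
      stringsAsFactors = FALSE
    )
    global <- global[order(global$metric), ]
    rownames(global) <- NULL
    nodal <- NULL
    if (!is.null(curves$nodal_mats)) {
      gu <- curves$grid_used
      nodal <- do.call(rbind, lapply(names(curves$nodal_mats), function(m) {
        V <- curves$nodal_mats[[m]]
        data.frame(node = colnames(V), metric = m,
                   auc = vapply(seq_len(ncol(V)),
                                function(j) safe_auc(V[, j], gu), numeric(1)),
                   stringsAsFactors = FALSE)
      }))
      nodal <- nodal[order(nodal$node, nodal$metric), ]
      rownames(nodal) <- NULL
    }
    return(list(global = global, nodal = nodal))
  }
  grid <- curves$grid
  g <- curves$global
  global <- do.call(rbind, lapply(split(g, g$metric), function(d) {
    d <- d[order(d$sparsity), ]
    data.frame(metric = d$metric[1],
               auc = safe_auc(d$value, d$sparsity),
               stringsAsFactors = FALSE)
  }))
  rownames(global) <- NULL
  nod <- curves$nodal
  if (is.null(nod)) return(list(global = global, nodal = NULL))
  long <- reshape_nodal_long(nod)
  nodal <- do.call(rbind, lapply(split(long, list(long$node, long$metric)),
    function(d) {
      d <- d[order(d$sparsity), ]
      data.frame(node = d$node[1], metric = d$metric[1],
                 auc = safe_auc(d$value, d$sparsity),
                 stringsAsFactors = FALSE)
    }))
  rownames(nodal) <- NULL
  list(global = global, nodal = nodal)
}

safe_auc <- function(values, grid) {
  tryCatch(suppressWarnings(metric_auc(values, grid)),
           error = function(e) NA_real_)
}

reshape_nodal_long <- function(nod) {
  mets <- c("degree", "betweenness", "efficiency", "clustering")
  do.call(rbind, lapply(mets, function(m) {
    data.frame(node = nod$node, sparsity = nod$sparsity, metric = m,
               value = as.numeric(nod[[m]]), stringsAsFactors = FALSE)
  }))
}
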