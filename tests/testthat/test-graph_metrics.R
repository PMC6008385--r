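test_that("binarization keeps the strongest edges at the requested count", {
  # 20 nodes at sparsity 0.05: round(9.5) rounds half away from zero
  C <- matrix(rnorm(400), 20, 20); C <- (C + t(C)) / 2; diag(C) <- 0
  A <- binarize_at_sparsity(C, 0.05)
  expect_equal(sum(A) / 2, 10)
  expect_true(all(A %in% 0:1))
  expect_identical(A, t(A))
  expect_equal(diag(A), rep(0L, 20))

  # sparsity 1 gives the complete graph
  expect_equal(sum(binarize_at_sparsity(C, 1)) / 2, 190)

  # 4-node worked example: only the two largest correlations survive
  C4 <- matrix(0, 4, 4)
  C4[upper.tri(C4)] <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  C4 <- C4 + t(C4)
  A4 <- binarize_at_sparsity(C4, 1 / 3)
  expect_equal(sum(A4) / 2, 2)
  expect_equal(A4[1, 2], 1L)  # r = 0.9
  expect_equal(A4[1, 3], 1L)  # r = 0.8
  expect_error(binarize_at_sparsity(C4, 1e-4), "zero edges")

  # signed ranking keeps large positive r over large |negative| r
  C4b <- C4; C4b[1, 2] <- C4b[2, 1] <- -0.95
  As <- binarize_at_sparsity(C4b, 1 / 6)
  expect_equal(As[1, 3], 1L)
  Aa <- binarize_at_sparsity(C4b, 1 / 6, rank = "abs")
  expect_equal(Aa[1, 2], 1L)
})

test_that("tie-breaking makes binarization deterministic on constant matrices", {
  C <- matrix(0.5, 6, 6); diag(C) <- 0
  A1 <- binarize_at_sparsity(C, 0.4)
  A2 <- binarize_at_sparsity(C, 0.4)
  expect_identical(A1, A2)
  expect_equal(sum(A1) / 2, 6)
})

test_that("closed-form fixtures: star, complete, triangle+pendant, disjoint edges", {
  st <- star4()
  expect_equal(path_length_harmonic(st), 4 / 3)
  expect_equal(global_efficiency(st), 0.75)
  expect_equal(clustering_coefficient(st)$cp, 0)
  expect_equal(local_efficiency(st), 0)
  nm <- nodal_metrics(st)
  expect_equal(nm$degree, c(3L, 1L, 1L, 1L))
  expect_equal(nm$betweenness, c(3, 0, 0, 0))
  expect_equal(nm$efficiency, c(1, 2 / 3, 2 / 3, 2 / 3))

  cm <- complete4()
  expect_equal(path_length_harmonic(cm), 1)
  expect_equal(global_efficiency(cm), 1)
  expect_equal(clustering_coefficient(cm)$cp, 1)
  expect_equal(local_efficiency(cm), 1)
  expect_equal(nodal_metrics(cm)$betweenness, rep(0, 4))

  tp <- tri_pendant()
  cc <- clustering_coefficient(tp)
  expect_equal(unname(cc$ci), c(1 / 3, 1, 1, 0))
  expect_equal(cc$cp, 7 / 12)
  expect_equal(local_efficiency(tp), 7 / 12)

  de <- generate_benchmark_graph("two_disjoint_edges")
  expect_equal(path_length_harmonic(de), 3)      # 12 / 4, no infinities
  expect_equal(global_efficiency(de), 1 / 3)
  expect_equal(largest_component_size(de), 2)

  pa <- generate_benchmark_graph("path", 4)
  expect_equal(nodal_metrics(pa)$betweenness, c(0, 2, 2, 0))

  expect_equal(largest_component_size(matrix(0L, 5, 5)), 1)
  expect_error(path_length_harmonic(matrix(0L, 3, 3)), "no edges")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    A <- random_graph(n, runif(1, 0.2, 0.8), seed = seed * 7)
    if (sum(A) == 0) next
    expect_equal(clustering_coefficient(A)$ci, oracle_clustering(A),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(global_efficiency(A), oracle_global_eff(A), tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_local_eff(A), tolerance = 1e-12)
    nm <- nodal_metrics(A)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-12)
    expect_equal(nm$efficiency, oracle_nodal_eff(A), tolerance = 1e-12)
    expect_equal(nm$degree, as.integer(rowSums(A)))
    if (any(is.finite(oracle_distances(A)[upper.tri(A)])))
      expect_equal(path_length_harmonic(A), oracle_lp_harmonic(A),
                   tolerance = 1e-12)
  }
})

test_that("adding an edge never increases a finite shortest-path distance", {
  set.seed(11)
  for (rep in 1:20) {
    A <- random_graph(8, 0.3, seed = 100 + rep)
    if (sum(A) == 0) next
    D1 <- oracle_distances(A)
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    e <- off[sample(nrow(off), 1), ]
    A2 <- A; A2[e[1], e[2]] <- A2[e[2], e[1]] <- 1L
    D2 <- oracle_distances(A2)
    expect_true(all(D2 <= D1 + 1e-12))
  }
})

test_that("degree-preserving rewiring keeps the degree sequence and randomizes", {
  rl <- generate_benchmark_graph("ring_lattice", 100, k = 6)
  cp0 <- clustering_coefficient(rl)$cp
  lower <- vapply(1:100, function(s) {
    B <- rewire_preserving_degree(rl, swaps_per_edge = 100, seed = s)
    expect_identical(rowSums(B), rowSums(rl))
    expect_equal(sum(B), sum(rl))
    clustering_coefficient(B)$cp < cp0
  }, logical(1))
  expect_gte(mean(lower), 0.95)

  # bit-exact reproducibility from the seed
  B1 <- rewire_preserving_degree(rl, seed = 42)
  B2 <- rewire_preserving_degree(rl, seed = 42)
  expect_identical(B1, B2)
  expect_error(rewire_preserving_degree(star4() * 0L), "at least 2 edges")
})

test_that("small-world parameters are 1 under self-comparison and reproducible", {
  A <- random_graph(20, 0.3, seed = 5)
  sw <- small_world_parameters(A, n_random = 1, swaps_per_edge = 0, seed = 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
  s1 <- small_world_parameters(A, n_random = 25, seed = 9)
  s2 <- small_world_parameters(A, n_random = 25, seed = 9)
  expect_identical(s1, s2)
})

test_that("metric curves cover the grid and match single-level computations", {
  set.seed(3)
  x <- matrix(rnorm(200 * 12), 200, 12)
  x[, 2] <- x[, 1] + rnorm(200, sd = 0.5)
  C <- fc_matrix(x)
  cur <- metric_curves(C, n_random = 0, seed = 1)
  expect_equal(sort(unique(cur$global$sparsity)), sparsity_grid())
  expect_equal(nrow(cur$global), 46 * 8)
  # spot-check against standalone functions at one level
  A <- binarize_at_sparsity(C, 0.20)
  g <- cur$global[cur$global$sparsity == 0.20, ]
  expect_equal(g$value[g$metric == "cp"], clustering_coefficient(A)$cp)
  expect_equal(g$value[g$metric == "lp"], path_length_harmonic(A))
  expect_equal(g$value[g$metric == "eglob"], global_efficiency(A))
  expect_equal(g$value[g$metric == "eloc"], local_efficiency(A))
  nd <- cur$nodal[cur$nodal$sparsity == 0.20, ]
  nm <- nodal_metrics(A)
  nd <- nd[match(nm$node, nd$node), ]
  expect_equal(nd$betweenness, nm$betweenness)
  expect_equal(as.integer(nd$degree), nm$degree)
  # deterministic under a seed when the ensemble is on
  c1 <- metric_curves(C, grid = c(0.1, 0.2, 0.3), n_random = 10, seed = 4)
  c2 <- metric_curves(C, grid = c(0.1, 0.2, 0.3), n_random = 10, seed = 4)
  expect_identical(c1$global, c2$global)
})

test_that("trapezoidal AUC matches closed forms and handles missing points", {
  grid <- sparsity_grid()
  expect_equal(metric_auc(rep(2, 46), grid), 2 * 0.45)
  expect_equal(metric_auc(grid, grid), (0.50^2 - 0.05^2) / 2)  # exact for linear
  expect_equal(metric_auc(c(1, 3), c(0.1, 0.2)), 0.2)
  vals <- rep(1, 46); vals[10] <- NA
  expect_warning(a <- metric_auc(vals, grid), "excluded")
  expect_equal(a, 0.45)
  expect_error(suppressWarnings(metric_auc(c(NA, 1, NA), c(1, 2, 3))),
               "fewer than 2")
})

test_that("metrics agree with igraph on larger graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    A <- random_graph(30, 0.2, seed = 900 + s)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(nodal_metrics(A)$betweenness,
                 unname(igraph::betweenness(g)), tolerance = 1e-10)
    ci_ig <- igraph::transitivity(g, type = "local")
    ci_ig[is.nan(ci_ig)] <- 0
    expect_equal(unname(clustering_coefficient(A)$ci), ci_ig,
                 tolerance = 1e-10)
    D <- igraph::distances(g)
    inv <- 1 / D; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    expect_equal(global_efficiency(A), mean(inv[row(inv) != col(inv)]),
                 tolerance = 1e-12)
  }
})
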