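test_that("group covariance construction injects delta only on affected edges", {
  # delta = 0: the two matrices are identical
  sp0 <- ground_truth_spec(delta = 0)
  cv0 <- build_group_covariances(sp0)
  expect_identical(cv0$group1, cv0$group2)

  # 3-node direct construction
  sp3 <- ground_truth_spec(n_nodes = 3, modules = rep("m", 3),
                           base_within_r = 0.5, base_between_r = 0.5,
                           affected_edges = matrix(c(1, 2), 1),
                           delta = -0.3)
  cv3 <- build_group_covariances(sp3)
  expect_equal(cv3$group2[1, 2], 0.2)
  expect_equal(cv3$group2[1, 3], 0.5)
  expect_equal(cv3$group2[2, 3], 0.5)
  expect_equal(diag(cv3$group2), rep(1, 3), ignore_attr = TRUE)

  # default 20-node 8/12 module split: both matrices positive definite
  cv <- build_group_covariances(ground_truth_spec())
  for (m in cv) {
    expect_identical(m, t(m))
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(ground_truth_spec(base_within_r = 0.9, delta = 0.2,
                                 modules = rep("m", 20),
                                 affected_edges = matrix(c(1, 2), 1)),
               "< 1")
})

test_that("positive-definiteness repair clips eigenvalues and renormalizes", {
  R <- matrix(0.9, 4, 4); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- -0.9   # inconsistent with the other 0.9 entries
  fixed <- dmnet:::nearest_pd_correlation(R)
  expect_gt(min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(fixed), rep(1, 4))
})

test_that("simulated series recover the innovation correlation", {
  cv <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  sim <- simulate_subject_timeseries(cv, t_points = 10000, ar_coef = 0,
                                     drift_amp = 0, nuisance_amp = 0, seed = 1)
  expect_equal(dim(sim$series), c(10000, 2))
  expect_lt(abs(cor(sim$series)[1, 2] - 0.6), 0.02)

  # identity covariance: mean |r| off-diagonal stays near the sampling bound
  I8 <- diag(8)
  sim2 <- simulate_subject_timeseries(I8, t_points = 4000, ar_coef = 0,
                                      drift_amp = 0, nuisance_amp = 0, seed = 2)
  r <- cor(sim2$series)
  expect_lt(mean(abs(r[upper.tri(r)])), 3 * 2 / sqrt(4000))

  # same seed, bit-identical output; AR filtering preserves correlation
  a <- simulate_subject_timeseries(cv, t_points = 500, seed = 7)
  b <- simulate_subject_timeseries(cv, t_points = 500, seed = 7)
  expect_identical(a, b)
  sim3 <- simulate_subject_timeseries(cv, t_points = 10000, ar_coef = 0.5,
                                      drift_amp = 0, nuisance_amp = 0, seed = 3)
  expect_lt(abs(cor(sim3$series)[1, 2] - 0.6), 0.03)
  expect_error(simulate_subject_timeseries(matrix(c(1, 1, 1, 1), 2), 100),
               "positive definite")
})

test_that("clinical variables reach their target correlation", {
  set.seed(10)
  x <- rnorm(100)
  y1 <- simulate_clinical(x, target_r = 1, seed = 1)
  expect_equal(cor(x, y1), 1)
  x0 <- rnorm(2000)
  y0 <- simulate_clinical(x0, target_r = 0, seed = 2)
  expect_lt(abs(cor(x0, y0)), 0.07)
  x5 <- rnorm(5000)
  y5 <- simulate_clinical(x5, target_r = -0.37, mean = 25, sd = 2, seed = 3)
  expect_lt(abs(cor(x5, y5) + 0.37), 0.03)
  expect_error(simulate_clinical(rep(1, 10), 0.5), "zero variance")
})

test_that("benchmark graphs match their named constructions", {
  cm <- generate_benchmark_graph("complete", 4)
  expect_equal(sum(cm) / 2, 6)
  expect_equal(rowSums(cm), rep(3, 4))
  st <- generate_benchmark_graph("star", 4)
  expect_equal(rowSums(st), c(3, 1, 1, 1))
  rl <- generate_benchmark_graph("ring_lattice", 10, k = 4)
  expect_equal(rowSums(rl), rep(4, 10))
  expect_error(generate_benchmark_graph("ring_lattice", 10, k = 3), "even k")
  er <- generate_benchmark_graph("erdos_renyi", 100, p = 0.16, seed = 8)
  m <- sum(er) / 2
  expect_lt(abs(m - 0.16 * 4950), 3 * sqrt(4950 * 0.16 * 0.84))
  expect_identical(er, generate_benchmark_graph("erdos_renyi", 100, p = 0.16,
                                                seed = 8))
})

test_that("cohort generation is seeded, labeled and motion-calibrated", {
  co <- simulate_cohort(n_per_group = 6, t_points = 60, seed = 21)
  expect_s3_class(co$subjects, "data.frame")
  expect_equal(nrow(co$subjects), 12)
  expect_equal(table(co$subjects$group)[["OSA"]], 6)
  expect_true(all(c("age", "BMI", "education", "AHI", "nadir_SaO2", "MoCA",
                    "delayed_memory", "ESS", "seed") %in% names(co$subjects)))
  expect_equal(dim(co$series[[1]]), c(60, 20))
  expect_equal(dim(co$motion[[1]]), c(60, 6))
  co2 <- simulate_cohort(n_per_group = 6, t_points = 60, seed = 21)
  expect_identical(co$series, co2$series)
  expect_identical(co$subjects, co2$subjects)
})

test_that("case-group clinical indices correlate with affected-edge connectivity", {
  co <- simulate_cohort(n_per_group = 40, t_points = 120, seed = 33,
                        clinical_targets = c(MoCA = -0.8))
  is_case <- co$subjects$group == "OSA"
  edge_fc <- vapply(co$subjects$subject_id[is_case], function(id)
    mean(fc_matrix(co$series[[id]])[co$spec$affected_edges]), numeric(1))
  r <- cor(edge_fc, co$subjects$MoCA[is_case])
  expect_lt(r, -0.4)   # strong target survives the rounding to 2 decimals
})
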