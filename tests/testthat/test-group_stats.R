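test_that("summary t-test reproduces published clinical statistics", {
  ahi <- summary_ttest(58.26, 20.37, 46, 2.51, 1.21, 46)
  expect_equal(ahi$t, 18.529, tolerance = 0.03 / 18.529)
  expect_equal(ahi$df, 90)
  st1 <- summary_ttest(31.28, 17.38, 46, 10.22, 3.72, 46)
  expect_lt(abs(st1$t - 8.037), 0.03)
  same <- summary_ttest(5, 1, 30, 5, 1, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(summary_ttest(1, 0, 10, 2, 0, 10), "zero variance")
  # equal-n pooled t coincides with the Welch-style formula
  welch <- (58.26 - 2.51) / sqrt(20.37^2 / 46 + 1.21^2 / 46)
  expect_equal(ahi$t, welch)
})

test_that("residualize returns covariate-orthogonal residuals", {
  set.seed(6)
  X <- cbind(age = rnorm(60, 40, 5), bmi = rnorm(60, 25, 3))
  y <- 2 * X[, 1] - 0.5 * X[, 2] + 3
  r <- residualize(y, X)
  expect_equal(max(abs(r)), 0, tolerance = 1e-8)
  y2 <- rnorm(60)
  r2 <- residualize(y2, X)
  expect_lt(max(abs(crossprod(cbind(1, X), r2))), 1e-8)
  expect_warning(residualize(y2, cbind(X, X[, 1])), "collinear")
})

test_that("covariate adjustment recovers the confound-free group contrast", {
  # a covariate that shifts both outcome and group: the adjusted t must sit
  # closer to the confound-free t than the unadjusted t does, on average
  set.seed(7)
  n <- 60
  res <- replicate(200, {
    group <- rep(c("A", "B"), each = n)
    conf <- rnorm(2 * n) + ifelse(group == "A", 1, 0)
    y_clean <- rnorm(2 * n) + ifelse(group == "A", 0.3, 0)
    y <- y_clean + 1.5 * conf
    subjects <- data.frame(subject_id = as.character(1:(2 * n)), group = group,
                           conf = conf, stringsAsFactors = FALSE)
    tbl <- function(v) data.frame(subject_id = subjects$subject_id,
                                  metric = "m", auc = v,
                                  stringsAsFactors = FALSE)
    t_free <- compare_groups_metric(tbl(y_clean), subjects, covariates = NULL)$t
    t_raw <- compare_groups_metric(tbl(y), subjects, covariates = NULL)$t
    t_adj <- compare_groups_metric(tbl(y), subjects, covariates = "conf")$t
    c(raw = abs(t_raw - t_free), adj = abs(t_adj - t_free))
  })
  expect_lt(mean(res["adj", ]), mean(res["raw", ]))
})

test_that("edgewise comparison is antisymmetric and sized C(n,2)", {
  set.seed(8)
  n_sub <- 20
  fc <- lapply(1:n_sub, function(i)
    fc_matrix(matrix(rnorm(60 * 20), 60, 20,
                     dimnames = list(NULL, paste0("n", 1:20)))))
  names(fc) <- sprintf("s%02d", 1:n_sub)
  subjects <- data.frame(subject_id = names(fc),
                         group = rep(c("A", "B"), each = 10),
                         age = rnorm(n_sub, 40, 5), stringsAsFactors = FALSE)
  ew <- compare_edgewise(fc, subjects, covariates = "age")
  expect_equal(nrow(ew), 190)
  ew_swapped <- compare_edgewise(fc, subjects, covariates = "age",
                                 group_levels = c("B", "A"))
  expect_equal(ew$t, -ew_swapped$t)
  expect_equal(ew$p, ew_swapped$p)

  # |r| = 1 entries are clipped before the z-transform, with a warning
  fc2 <- fc
  fc2[[1]][1, 2] <- fc2[[1]][2, 1] <- 1
  expect_warning(compare_edgewise(fc2, subjects, covariates = NULL), "clipped")
})

test_that("nodal comparison applies the per-family Bonferroni multiplier", {
  set.seed(9)
  n_sub <- 24
  nodes <- paste0("n", 1:20)
  nodal <- expand.grid(subject_id = sprintf("s%02d", 1:n_sub), node = nodes,
                       metric = c("betweenness", "degree", "efficiency"),
                       stringsAsFactors = FALSE)
  nodal$auc <- rnorm(nrow(nodal))
  subjects <- data.frame(subject_id = sprintf("s%02d", 1:n_sub),
                         group = rep(c("A", "B"), each = 12),
                         stringsAsFactors = FALSE)
  out <- compare_nodal(nodal, subjects, covariates = NULL)
  expect_equal(nrow(out), 60)
  expect_equal(out$p_bonf, pmin(1, out$p * 20))
  expect_true(all(out$p_bonf >= out$p))
  # raw p = 0.004 with 20 nodes: only uncorrected-significant
  expect_equal(min(1, 0.004 * 20), 0.08)
  row <- out[which.min(out$p), ]
  if (row$p < 0.0025) expect_true(row$sig_bonf) else expect_false(row$sig_bonf)
})

test_that("abnormal-connectivity composite averages raw r over listed edges", {
  fc <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  fc[upper.tri(fc)] <- 0.5
  fc <- fc + t(fc)
  edges <- cbind(c("n1", "n2"), c("n3", "n4"))
  expect_equal(abnormal_fc_score(fc, edges), 0.5)
  fc2 <- fc
  fc2["n1", "n3"] <- fc2["n3", "n1"] <- 0.2
  fc2["n2", "n4"] <- fc2["n4", "n2"] <- -0.2
  expect_equal(abnormal_fc_score(fc2, edges), 0)
  # an 18-edge set equals the hand-computed mean
  set.seed(10)
  big <- fc_matrix(matrix(rnorm(40 * 10), 40, 10,
                          dimnames = list(NULL, paste0("r", 1:10))))
  pairs <- which(upper.tri(big), arr.ind = TRUE)[1:18, ]
  e18 <- cbind(rownames(big)[pairs[, 1]], colnames(big)[pairs[, 2]])
  expect_equal(abnormal_fc_score(big, e18), mean(big[pairs]))
  expect_error(abnormal_fc_score(fc, edges[0, , drop = FALSE]), "empty")
})

test_that("clinical correlation returns Pearson r with t-based p", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate_clinical(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_clinical(x, -x)$r, -1)
  set.seed(11)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  ct <- correlate_clinical(a, b)
  ref <- cor.test(a, b)
  expect_equal(ct$r, unname(ref$estimate))
  expect_equal(ct$p, ref$p.value)
  b[3] <- NA
  expect_equal(correlate_clinical(a, b)$n, 49)
  expect_error(correlate_clinical(a, rep(1, 50)), "zero-variance")
})
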