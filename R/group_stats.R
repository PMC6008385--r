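#' Two-sample t-test from summary statistics
#'
#' Pooled-variance independent two-sample t-test computed from group
#' means, standard deviations and sizes (the form reconstructable from
#' published summary tables). With equal group sizes the pooled and
#' Welch statistics coincide:
#' `t = (m1 - m2) / sqrt(s1^2/n + s2^2/n)`, `df = n1 + n2 - 2`.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both groups have zero variance")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Recompute t statistics for the bundled clinical summaries
#'
#' Applies [summary_ttest()] to every row of [clinical_reference()],
#' returning the recomputed statistic next to the published one.
#'
#' @return Data frame: `variable`, `t`, `df`, `p`, `t_published`.
#' @export
clinical_reference_ttests <- function() {
  ref <- clinical_reference()
  res <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    tt <- summary_ttest(r$mean_osa, r$sd_osa, r$n_osa,
                        r$mean_gs, r$sd_gs, r$n_gs)
    data.frame(variable = r$variable, t = tt$t, df = tt$df, p = tt$p,
               t_published = r$t_published, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Residualize values on covariates
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus
#' the covariates, fitted on the pooled sample (both groups together)
#' so that group-specific covariate slopes do not enter the contrast.
#' Collinear covariates are dropped with a warning.
#'
#' @param values numeric vector.
#' @param covariates data frame or matrix of covariates (rows =
#'   subjects), or `NULL` for a no-op.
#' @return Residual vector (zero mean, orthogonal to the covariates).
#' @export
residualize <- function(values, covariates) {
  if (is.null(covariates)) return(values - mean(values))
  X <- cbind(intercept = 1, as.matrix(covariates))
  stopifnot(nrow(X) == length(values))
  if (length(values) <= ncol(X)) stop("need more subjects than covariates + 1")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  as.numeric(values - X %*% qr.coef(qrx, values))
}

# Column-wise pooled two-sample t on a subjects x units matrix.
# Positive t means group 1 > group 2.
pooled_t_cols <- function(Y, idx1, idx2, var_equal = TRUE) {
  Y <- as.matrix(Y)
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- colMeans(Y[idx1, , drop = FALSE])
  m2 <- colMeans(Y[idx2, , drop = FALSE])
  v1 <- colSums(sweep(Y[idx1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(Y[idx2, , drop = FALSE], 2, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(t_stat))
  } else {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  data.frame(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

# Covariate-adjusted group contrast: t statistic of the group
# coefficient in the joint model y ~ intercept + group + covariates,
# column-wise over a subjects x units matrix. Equivalent (by
# Frisch-Waugh-Lovell) to residualizing both the outcome and the group
# indicator on the covariates, with the correct residual df; the naive
# residualize-then-t-test shortcut is conservative whenever a covariate
# is correlated with group membership. Without covariates this is
# exactly the pooled two-sample t. Positive t means group 1 > group 2.
adjusted_group_t <- function(Y, idx1, idx2, X = NULL, var_equal = TRUE) {
  Y <- as.matrix(Y)
  if (is.null(X) && !var_equal) return(pooled_t_cols(Y, idx1, idx2, FALSE))
  n <- nrow(Y)
  g <- numeric(n)
  g[idx1] <- 0.5; g[idx2] <- -0.5   # contrast coded: coef = mean1 - mean2
  D <- cbind(intercept = 1, group = g, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    dropped <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    if ("group" %in% dropped) stop("group indicator collinear with covariates")
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    D <- D[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(D)
  }
  coefs <- qr.coef(qrd, Y)
  res <- Y - D %*% coefs
  df <- n - ncol(D)
  sigma2 <- colSums(res^2) / df
  R <- qr.R(qrd)   # columns may be pivoted; locate the group column
  gi <- match("group", colnames(R))
  gg <- chol2inv(R)[gi, gi]         # (D'D)^-1 entry of the group column
  t_stat <- coefs["group", ] / sqrt(sigma2 * gg)
  data.frame(t = as.numeric(t_stat), df = df,
             p = 2 * pt(-abs(as.numeric(t_stat)), df))
}

group_indices <- function(subjects, group_levels = NULL) {
  g <- subjects$group
  if (is.null(group_levels)) group_levels <- unique(g)
  stopifnot(length(group_levels) == 2)
  list(levels = group_levels,
       idx1 = which(g == group_levels[1]),
       idx2 = which(g == group_levels[2]))
}

covariate_matrix <- function(subjects, covariates) {
  if (is.null(covariates) || length(covariates) == 0) return(NULL)
  missing_cov <- setdiff(covariates, names(subjects))
  if (length(missing_cov)) stop("unknown covariate(s): ",
                                paste(missing_cov, collapse = ", "))
  as.matrix(subjects[, covariates, drop = FALSE])
}

#' Group comparison of global metric AUCs
#'
#' For each global network metric, compares per-subject AUCs between
#' groups with covariate effects diminished: the reported t is the
#' group-coefficient t-test of the joint linear model
#' `auc ~ group + covariates` (equivalent to double residualization on
#' the covariates, and exactly the pooled two-sample t when no
#' covariates are given). Positive t means the first group level
#' exceeds the second; group levels default to their order of
#' appearance in `subjects`.
#'
#' @param auc_tbl data frame `subject_id`, `metric`, `auc` (one row per
#'   subject x metric); subjects with missing AUC are excluded with a
#'   message.
#' @param subjects subject table with `subject_id`, `group` and any
#'   covariate columns.
#' @param covariates character vector of covariate column names, or
#'   `NULL` to disable adjustment.
#' @param group_levels optional explicit ordering of the two groups.
#' @param var_equal pooled (default) vs Welch variance.
#' @return Data frame: `metric`, `t`, `df`, `p`.
#' @export
compare_groups_metric <- function(auc_tbl, subjects,
                                  covariates = c("age", "BMI", "education"),
                                  group_levels = NULL, var_equal = TRUE) {
  res <- lapply(split(auc_tbl, auc_tbl$metric), function(d) {
    metric <- d$metric[1]
    d <- d[match(subjects$subject_id, d$subject_id), ]
    ok <- is.finite(d$auc)
    sub <- subjects[ok, , drop = FALSE]
    if (length(unique(sub$group)) < 2 || min(table(sub$group)) < 2) {
      message("metric ", metric, ": too few subjects with finite AUC; skipped")
      return(data.frame(metric = metric, t = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    if (any(!ok)) message(sum(!ok), " subject(s) excluded for metric ",
                          metric, " (missing AUC)")
    gi <- group_indices(sub, group_levels)
    tt <- adjusted_group_t(matrix(d$auc[ok], ncol = 1), gi$idx1, gi$idx2,
                           covariate_matrix(sub, covariates), var_equal)
    data.frame(metric = metric, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Edgewise group comparison of connectivity
#'
#' For every unordered node pair, applies the Fisher z-transform to the
#' correlations (variance stabilization; values at |r| = 1 are clipped
#' to 1 - 1e-7 with a warning) and runs the covariate-adjusted
#' two-sample comparison (see [compare_groups_metric()]). Flagged at
#' `p < alpha`, uncorrected.
#'
#' @param fc_list named list of connectivity matrices (shared labels),
#'   in `subjects$subject_id` order or keyed by id.
#' @param subjects subject table.
#' @param covariates covariate column names or `NULL`.
#' @param alpha uncorrected significance level.
#' @param fisher_z apply the z-transform before testing (default TRUE;
#'   the composite score in [abnormal_fc_score()] always uses raw r).
#' @param group_levels,var_equal see [compare_groups_metric()].
#' @return Data frame with one row per node pair: `region1`, `region2`,
#'   `t`, `df`, `p`, `significant`.
#' @export
compare_edgewise <- function(fc_list, subjects,
                             covariates = c("age", "BMI", "education"),
                             alpha = 0.05, fisher_z = TRUE,
                             group_levels = NULL, var_equal = TRUE) {
  ids <- subjects$subject_id
  if (!is.null(names(fc_list))) fc_list <- fc_list[ids]
  labels <- rownames(fc_list[[1]]) %||% paste0("n", seq_len(nrow(fc_list[[1]])))
  n <- length(labels)
  ut <- which(upper.tri(fc_list[[1]]))
  E <- t(vapply(fc_list, function(m) m[ut], numeric(length(ut))))
  if (fisher_z) {
    clipped <- abs(E) >= 1
    if (any(clipped)) {
      warning(sum(clipped), " correlation(s) at |r| >= 1 clipped before z-transform")
      E[clipped] <- sign(E[clipped]) * (1 - 1e-7)
    }
    E <- atanh(E)
  }
  gi <- group_indices(subjects, group_levels)
  tt <- adjusted_group_t(E, gi$idx1, gi$idx2,
                         covariate_matrix(subjects, covariates), var_equal)
  pair <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- data.frame(region1 = labels[pair[, 1]], region2 = labels[pair[, 2]],
                    t = tt$t, df = tt$df, p = tt$p,
                    significant = tt$p < alpha, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Nodal metric group comparison with Bonferroni correction
#'
#' Covariate-adjusted two-sample t-tests of per-node AUCs for each
#' nodal metric family (betweenness, degree, efficiency). The Bonferroni
#' multiplier is the number of nodes, applied within each metric
#' family and capped at 1; both the uncorrected and corrected
#' significance flags are returned.
#'
#' @param nodal_auc data frame `subject_id`, `node`, `metric`, `auc`.
#' @param subjects subject table.
#' @param covariates covariate column names or `NULL`.
#' @param alpha significance level.
#' @param metrics metric families to test.
#' @param group_levels,var_equal see [compare_groups_metric()].
#' @return Data frame: `node`, `metric`, `t`, `df`, `p`, `p_bonf`,
#'   `sig_uncorrected`, `sig_bonf`.
#' @export
compare_nodal <- function(nodal_auc, subjects,
                          covariates = c("age", "BMI", "education"),
                          alpha = 0.05,
                          metrics = c("betweenness", "degree", "efficiency"),
                          group_levels = NULL, var_equal = TRUE) {
  gi <- group_indices(subjects, group_levels)
  X <- covariate_matrix(subjects, covariates)
  res <- lapply(metrics, function(m) {
    d <- nodal_auc[nodal_auc$metric == m, ]
    wide <- do.call(cbind, lapply(split(d, d$node), function(s)
      s$auc[match(subjects$subject_id, s$subject_id)]))
    n_nodes <- ncol(wide)
    tt <- adjusted_group_t(wide, gi$idx1, gi$idx2, X, var_equal)
    data.frame(node = colnames(wide), metric = m, t = tt$t, df = tt$df,
               p = tt$p, p_bonf = pmin(1, tt$p * n_nodes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$sig_uncorrected <- out$p < alpha
  out$sig_bonf <- out$p_bonf < alpha
  rownames(out) <- NULL
  out
}

#' Composite abnormal-connectivity score
#'
#' Per-subject unweighted mean of the raw correlation coefficients over
#' the edges that showed significant between-group differences.
#'
#' @param fc one subject's connectivity matrix.
#' @param edges two-column matrix/data frame of node names or indices
#'   (e.g. `region1`/`region2` of the significant rows of
#'   [compare_edgewise()]).
#' @return Scalar score.
#' @export
abnormal_fc_score <- function(fc, edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  if (nrow(edges) == 0) stop("empty significant-edge set")
  if (is.character(edges)) {
    idx <- cbind(match(edges[, 1], rownames(fc)), match(edges[, 2], rownames(fc)))
    if (any(is.na(idx))) stop("edge names not found in connectivity matrix")
  } else idx <- edges
  mean(fc[idx])
}

#' Pearson correlation between a network measure and a clinical index
#'
#' Sample Pearson r with the two-sided t-based p-value; pairs with
#' missing values are dropped.
#'
#' @param x,y paired per-subject values (>= 3 complete pairs).
#' @return List with `r`, `p`, `n`.
#' @export
correlate_clinical <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
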