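#' Ground-truth specification for a two-group synthetic cohort
#'
#' Defines the target correlation structure of the simulated DMN:
#' a modular correlation matrix (higher within-module than
#' between-module correlation) for the control group, and a copy with a
#' signed change `delta` applied to a set of affected edges for the
#' case group. Defaults mirror a 20-node DMN split into an anterior
#' subsystem (8 nodes) and a posterior subsystem (12 nodes), with 8
#' posterior edges attenuated in the case group.
#'
#' @param n_nodes number of network nodes.
#' @param modules character vector of module labels, one per node;
#'   defaults to the anterior/posterior split of the packaged 20-node
#'   DMN parcellation.
#' @param node_names node labels; default the packaged ROI names.
#' @param base_within_r,base_between_r within/between-module target
#'   correlations, both in (0, 1).
#' @param affected_edges two-column matrix (or list of pairs) of node
#'   names or indices whose correlation is altered in group 2.
#' @param delta signed correlation change on affected edges.
#' @param ar_coef lag-1 autoregressive coefficient of the simulated
#'   signals, in \[0, 1).
#' @param seed integer seed recorded with the spec.
#' @return Object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(n_nodes = 20,
                              modules = NULL,
                              node_names = NULL,
                              base_within_r = 0.45,
                              base_between_r = 0.15,
                              affected_edges = NULL,
                              delta = -0.25,
                              ar_coef = 0.3,
                              seed = 1L) {
  if (n_nodes == 20 && is.null(node_names)) node_names <- dmn_rois()$name
  if (is.null(node_names)) node_names <- paste0("n", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes)
  if (is.null(modules)) {
    if (n_nodes == 20) modules <- dmn_default_modules(node_names)
    else modules <- rep("all", n_nodes)
  }
  stopifnot(length(modules) == n_nodes)
  if (is.null(affected_edges) && n_nodes == 20)
    affected_edges <- dmn_default_affected_edges()
  affected_edges <- normalize_edges(affected_edges, node_names)
  stopifnot(base_within_r > 0, base_within_r < 1,
            base_between_r > 0, base_between_r < 1,
            ar_coef >= 0, ar_coef < 1)
  base <- ifelse(apply(affected_edges, 1, function(e) modules[e[1]] == modules[e[2]]),
                 base_within_r, base_between_r)
  if (any(abs(base + delta) >= 1))
    stop("|base correlation + delta| must be < 1 on every affected edge")
  structure(list(n_nodes = n_nodes, modules = modules,
                 node_names = node_names,
                 base_within_r = base_within_r,
                 base_between_r = base_between_r,
                 affected_edges = affected_edges, delta = delta,
                 ar_coef = ar_coef, seed = as.integer(seed)),
            class = "ground_truth_spec")
}

# Anterior subsystem: medial prefrontal + lateral/polar temporal nodes;
# posterior: PCC, parietal, retrosplenial, parahippocampal, hippocampal.
dmn_default_modules <- function(node_names) {
  anterior <- c("aMPFC.L", "aMPFC.R", "dMPFC", "vMPFC",
                "TempP.L", "TempP.R", "LTC.L", "LTC.R")
  ifelse(node_names %in% anterior, "anterior", "posterior")
}

# Eight posterior-module edges altered in the case group; mirrors the
# PCC/retrosplenial/hippocampal axis where case-control differences are
# typically reported.
dmn_default_affected_edges <- function() {
  rbind(c("PCC.L", "HF.L"), c("PCC.L", "HF.R"),
        c("PCC.R", "HF.L"), c("PCC.R", "HF.R"),
        c("PCC.L", "Rsp.L"), c("Rsp.L", "pIPL.L"),
        c("HF.R", "TPJ.R"), c("HF.R", "pIPL.R"))
}

normalize_edges <- function(edges, node_names) {
  if (is.null(edges)) return(matrix(integer(0), 0, 2))
  if (is.list(edges)) edges <- do.call(rbind, edges)
  if (is.character(edges)) {
    idx <- matrix(match(edges, node_names), ncol = 2)
    if (any(is.na(idx))) stop("unknown node name in affected_edges")
  } else idx <- matrix(as.integer(edges), ncol = 2)
  if (any(idx[, 1] == idx[, 2])) stop("affected edge joins a node to itself")
  t(apply(idx, 1, sort))
}

#' Target correlation matrices for the two groups
#'
#' Group 1 uses the base within/between-module correlations; group 2 is
#' identical except that `delta` is added on the affected edges. Both
#' matrices are repaired to positive definiteness if needed (eigenvalue
#' clipping at 1e-6 followed by re-normalization to unit diagonal) —
#' naive delta injection can otherwise break positive definiteness.
#'
#' @param spec a [ground_truth_spec()].
#' @return List with elements `group1` and `group2` (correlation
#'   matrices with node-name dimnames).
#' @export
build_group_covariances <- function(spec) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  n <- spec$n_nodes
  same <- outer(spec$modules, spec$modules, "==")
  R1 <- ifelse(same, spec$base_within_r, spec$base_between_r)
  diag(R1) <- 1
  dimnames(R1) <- list(spec$node_names, spec$node_names)
  R2 <- R1
  if (nrow(spec$affected_edges) > 0) {
    for (r in seq_len(nrow(spec$affected_edges))) {
      i <- spec$affected_edges[r, 1]; j <- spec$affected_edges[r, 2]
      R2[i, j] <- R2[j, i] <- R1[i, j] + spec$delta
    }
  }
  list(group1 = nearest_pd_correlation(R1), group2 = nearest_pd_correlation(R2))
}

# Eigenvalue clipping at `floor`, then rescale to unit diagonal; a few
# passes because the rescaling can nudge the spectrum. Errors with the
# offending eigenvalues if the repair does not converge.
nearest_pd_correlation <- function(R, floor = 1e-6, max_iter = 20) {
  for (it in seq_len(max_iter)) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) > 0) return(R)
    vals <- pmax(e$values, floor)
    R <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
    R <- (R + t(R)) / 2
  }
  e <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 0)
    stop("correlation matrix not positive definite after repair; eigenvalues: ",
         paste(signif(e[e <= 0], 4), collapse = ", "))
  R
}

#' Simulate one subject's ROI time series
#'
#' Generates a Gaussian lag-1 autoregressive multivariate series whose
#' innovation correlation is `cov_mat`: with a common AR coefficient the
#' stationary cross-correlation structure equals the innovation
#' correlation. Optional linear drift and shared nuisance signals
#' (white-matter-, CSF- and global-like confounds) are added on top,
#' and a bounded-random-walk 6-parameter motion trace is produced.
#'
#' @param cov_mat positive definite correlation matrix (N x N).
#' @param t_points number of volumes (>= 2 N).
#' @param tr repetition time in seconds.
#' @param ar_coef lag-1 AR coefficient in \[0, 1).
#' @param drift_amp amplitude of the per-node linear drift (signal-sd
#'   units over the scan; 0 disables).
#' @param nuisance_amp amplitude of the shared nuisance contamination
#'   (0 disables).
#' @param motion_amp standard deviation of per-volume motion steps
#'   (mm / degrees); larger values raise the QC-failure rate.
#' @param seed integer seed; identical seeds give identical output.
#' @return List with `series` (T x N matrix), `motion` (T x 6 matrix:
#'   3 translations mm, 3 rotations degrees), and `nuisance` (T x 3
#'   matrix: wm, csf, global).
#' @export
simulate_subject_timeseries <- function(cov_mat, t_points = 230, tr = 2,
                                        ar_coef = 0.3, drift_amp = 1,
                                        nuisance_amp = 1, motion_amp = 0.05,
                                        seed = NULL) {
  n <- nrow(cov_mat)
  stopifnot(t_points >= 2 * n)
  ev <- eigen(cov_mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix is not positive definite")
  with_seed(seed, {
    L <- chol(cov_mat)
    burn <- 50
    innov <- matrix(rnorm((t_points + burn) * n), t_points + burn, n) %*% L
    if (ar_coef > 0) {
      x <- stats::filter(innov, filter = ar_coef, method = "recursive")
      x <- matrix(as.numeric(x), t_points + burn, n)
    } else x <- innov
    series <- x[(burn + 1):(burn + t_points), , drop = FALSE]

    tt <- seq_len(t_points)
    if (drift_amp > 0) {
      slopes <- rnorm(n, sd = drift_amp)
      series <- series + outer((tt - mean(tt)) / t_points, slopes)
    }
    nuis <- sapply(1:3, function(k) {
      z <- stats::filter(rnorm(t_points + burn), 0.5, method = "recursive")
      as.numeric(z)[(burn + 1):(burn + t_points)]
    })
    colnames(nuis) <- c("wm", "csf", "global")
    if (nuisance_amp > 0) {
      load <- matrix(rnorm(3 * n, sd = nuisance_amp / sqrt(3)), 3, n)
      series <- series + nuis %*% load
    }
    motion <- simulate_motion_trace(t_points, step_sd = motion_amp)
    colnames(series) <- rownames(cov_mat)
    list(series = series, motion = motion, nuisance = nuis)
  })
}

#' Simulate a 6-parameter rigid-body motion trace
#'
#' Bounded Gaussian random walk for 3 translations (mm) and 3 rotations
#' (degrees); a soft tanh bound keeps excursions finite so `step_sd`
#' smoothly controls how often the motion QC thresholds are exceeded.
#'
#' @param t_points number of volumes.
#' @param step_sd per-volume step standard deviation.
#' @param bound soft bound on absolute excursion.
#' @return T x 6 matrix, columns `trans_x..trans_z`, `rot_x..rot_z`.
#' @export
simulate_motion_trace <- function(t_points, step_sd = 0.05, bound = 3) {
  walk <- apply(matrix(rnorm(t_points * 6, sd = step_sd), t_points, 6), 2, cumsum)
  m <- bound * tanh(walk / bound)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate a clinical variable correlated with a network metric
#'
#' Constructs `y = r * z(x) + sqrt(1 - r^2) * noise`, rescaled to the
#' requested mean and standard deviation, so the population correlation
#' between the returned vector and `metric_values` is exactly
#' `target_r`.
#'
#' @param metric_values per-subject metric scalars (>= 3, non-constant).
#' @param target_r desired population correlation in \[-1, 1\].
#' @param mean,sd location and scale of the returned variable.
#' @param seed integer seed.
#' @return Numeric vector of the same length as `metric_values`.
#' @export
simulate_clinical <- function(metric_values, target_r, mean = 0, sd = 1,
                              seed = NULL) {
  stopifnot(abs(target_r) <= 1, length(metric_values) >= 3)
  if (sd(metric_values) == 0) stop("metric_values has zero variance")
  z <- as.numeric(scale(metric_values))
  with_seed(seed, {
    noise <- rnorm(length(z))
    y <- target_r * z + sqrt(1 - target_r^2) * noise
    mean + sd * y
  })
}

#' Deterministic benchmark graphs
#'
#' Small named graphs used as fixtures for topology metrics: complete,
#' star (node 1 is the hub), path, ring lattice (each node linked to its
#' `k` nearest neighbors, `k` even), Erdos-Renyi `G(n, p)`, and two
#' disjoint edges on 4 nodes.
#'
#' @param kind one of `"complete"`, `"star"`, `"path"`,
#'   `"ring_lattice"`, `"erdos_renyi"`, `"two_disjoint_edges"`.
#' @param n number of nodes.
#' @param k neighbor count for the ring lattice (even).
#' @param p edge probability for Erdos-Renyi.
#' @param seed integer seed (Erdos-Renyi only).
#' @return Binary adjacency matrix.
#' @export
generate_benchmark_graph <- function(kind = c("complete", "star", "path",
                                              "ring_lattice", "erdos_renyi",
                                              "two_disjoint_edges"),
                                     n = 4, k = 2, p = 0.1, seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "two_disjoint_edges") n <- 4
  A <- matrix(0L, n, n)
  switch(kind,
    complete = { A[] <- 1L; diag(A) <- 0L },
    star = { A[1, 2:n] <- 1L; A[2:n, 1] <- 1L },
    path = for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L,
    ring_lattice = {
      if (k %% 2 != 0) stop("ring lattice requires even k")
      stopifnot(k < n)
      for (i in seq_len(n)) for (d in seq_len(k / 2)) {
        j <- ((i - 1 + d) %% n) + 1
        A[i, j] <- A[j, i] <- 1L
      }
    },
    erdos_renyi = {
      A <- with_seed(seed, {
        up <- which(upper.tri(A))
        draw <- runif(length(up)) < p
        A[up[draw]] <- 1L
        A + t(A)
      })
    },
    two_disjoint_edges = { A[1, 2] <- A[2, 1] <- 1L; A[3, 4] <- A[4, 3] <- 1L }
  )
  storage.mode(A) <- "integer"
  A
}

#' Generate a full two-group synthetic cohort
#'
#' Simulates `n_per_group` subjects per group from the group target
#' correlation matrices of `spec`, with drift, nuisance contamination
#' and motion traces, and attaches demographic covariates and clinical
#' indices. Clinical indices in the case group are generated with a
#' target correlation to each subject's mean connectivity over the
#' affected edges, so downstream correlation analyses have a known
#' recoverable structure; control-group indices are drawn from their
#' group reference distribution without metric coupling.
#'
#' @param n_per_group subjects per group.
#' @param t_points volumes per subject.
#' @param tr repetition time, seconds.
#' @param spec a [ground_truth_spec()].
#' @param drift_amp,nuisance_amp,motion_amp passed to
#'   [simulate_subject_timeseries()].
#' @param clinical_targets named numeric vector of target correlations
#'   between case-group clinical indices and the affected-edge mean
#'   connectivity; names must appear in [clinical_reference()].
#' @param seed master seed; all per-subject seeds derive from it.
#' @return List of class `dmn_cohort`: `subjects` data frame (ids,
#'   group, covariates, clinical indices, per-subject seeds), `series`,
#'   `motion`, `nuisance` lists keyed by subject id, `spec`, and the
#'   two group covariance matrices.
#' @export
simulate_cohort <- function(n_per_group = 46, t_points = 230, tr = 2,
                            spec = ground_truth_spec(),
                            drift_amp = 1, nuisance_amp = 1,
                            motion_amp = 0.05,
                            clinical_targets = c(MoCA = -0.35,
                                                 delayed_memory = -0.30,
                                                 nadir_SaO2 = 0.32),
                            seed = 1L) {
  covs <- build_group_covariances(spec)
  n_tot <- 2 * n_per_group
  ids <- sprintf("sub-%03d", seq_len(n_tot))
  group <- rep(c("OSA", "GS"), each = n_per_group)
  sub_seed <- vapply(seq_len(n_tot), function(i) derive_seed(seed, i), integer(1))

  series <- motion <- nuisance <- vector("list", n_tot)
  names(series) <- names(motion) <- names(nuisance) <- ids
  for (i in seq_len(n_tot)) {
    cm <- if (group[i] == "OSA") covs$group2 else covs$group1
    sim <- simulate_subject_timeseries(cm, t_points = t_points, tr = tr,
                                       ar_coef = spec$ar_coef,
                                       drift_amp = drift_amp,
                                       nuisance_amp = nuisance_amp,
                                       motion_amp = motion_amp,
                                       seed = sub_seed[i])
    series[[i]] <- sim$series
    motion[[i]] <- sim$motion
    nuisance[[i]] <- sim$nuisance
  }

  ref <- clinical_reference()
  subjects <- with_seed(derive_seed(seed, 900001L), {
    df <- data.frame(subject_id = ids, group = group,
                     age = round(rnorm(n_tot, 39, 7), 1),
                     education = round(pmax(6, rnorm(n_tot, 12, 3))),
                     stringsAsFactors = FALSE)
    df$BMI <- round(group_draw(ref, "BMI", group), 2)
    df
  })

  # case-group clinical indices carry a target correlation with the
  # subject's mean raw connectivity over the ground-truth affected edges
  edge_fc <- vapply(seq_len(n_tot), function(i) {
    fc <- fc_matrix(series[[i]])
    mean(fc[spec$affected_edges])
  }, numeric(1))
  is_case <- group == "OSA"
  k <- 0L
  for (v in c("AHI", "nadir_SaO2", "MoCA", "delayed_memory", "ESS")) {
    k <- k + 1L
    r <- ref[ref$variable == v, ]
    target <- if (v %in% names(clinical_targets)) clinical_targets[[v]] else 0
    case_vals <- simulate_clinical(edge_fc[is_case], target,
                                   mean = r$mean_osa, sd = r$sd_osa,
                                   seed = derive_seed(seed, 910000L + k))
    ctrl_vals <- with_seed(derive_seed(seed, 920000L + k),
                           rnorm(sum(!is_case), r$mean_gs, r$sd_gs))
    subjects[[v]] <- NA_real_
    subjects[[v]][is_case] <- round(case_vals, 2)
    subjects[[v]][!is_case] <- round(ctrl_vals, 2)
  }
  subjects$seed <- sub_seed

  structure(list(subjects = subjects, series = series, motion = motion,
                 nuisance = nuisance, spec = spec, covariances = covs,
                 tr = tr, seed = as.integer(seed)),
            class = "dmn_cohort")
}

group_draw <- function(ref, variable, group) {
  r <- ref[ref$variable == variable, ]
  mu <- ifelse(group == "OSA", r$mean_osa, r$mean_gs)
  sig <- ifelse(group == "OSA", r$sd_osa, r$sd_gs)
  rnorm(length(group), mu, sig)
}

#' Bundled clinical reference summaries
#'
#' Group summary statistics (mean, SD, n = 46 per group) of the
#' demographic, polysomnographic and cognitive measures of a severe
#' obstructive-sleep-apnea vs good-sleeper case-control sample, with the
#' published two-sample t statistics. Used as generator defaults for
#' [simulate_cohort()] and as worked examples for
#' [summary_ttest()].
#'
#' @return Data frame with columns `variable`, `mean_osa`, `sd_osa`,
#'   `mean_gs`, `sd_gs`, `n_osa`, `n_gs`, `t_published`.
#' @export
clinical_reference <- function() {
  path <- system.file("extdata", "clinical_reference.csv", package = "dmnet")
  if (path == "") stop("packaged clinical reference table not found")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' One TSV per subject (T rows x N node columns, header = node names),
#' a 6-column whitespace-delimited motion file per subject, a
#' `subjects.csv` manifest, and a `ground_truth.json` describing the
#' generating specification.
#'
#' @param cohort a `dmn_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dmn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in cohort$subjects$subject_id) {
    write.table(cohort$series[[id]], file.path(dir, paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cohort$motion[[id]], file.path(dir, paste0(id, "_motion.txt")),
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(cohort$nuisance[[id]], file.path(dir, paste0(id, "_nuisance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  gt <- cohort$spec
  gt$affected_edges <- apply(gt$affected_edges, 1, function(e)
    gt$node_names[e])
  jsonlite::write_json(
    c(unclass(gt), list(tr = cohort$tr, master_seed = cohort$seed)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `subjects`, `series`, `motion`, `nuisance`.
#' @export
read_cohort <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  series <- motion <- nuisance <- list()
  for (id in subjects$subject_id) {
    series[[id]] <- as.matrix(read.delim(file.path(dir, paste0(id, ".tsv")),
                                         check.names = FALSE))
    motion[[id]] <- as.matrix(read.table(file.path(dir, paste0(id, "_motion.txt"))))
    nuisance[[id]] <- as.matrix(read.delim(file.path(dir, paste0(id, "_nuisance.tsv"))))
  }
  list(subjects = subjects, series = series, motion = motion,
       nuisance = nuisance)
}
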