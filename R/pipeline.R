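#' Run configuration
#'
#' Validates and freezes the tunable parameters of an end-to-end run.
#' A serialized copy is written into every output directory so results
#' are reproducible from config + seed alone.
#'
#' @param grid sparsity grid (see [sparsity_grid()]).
#' @param n_random null-ensemble size per sparsity level.
#' @param swaps_per_edge rewiring effort per null network.
#' @param edge_rank `"signed"` or `"abs"` edge ranking for
#'   binarization.
#' @param covariates covariate column names used for adjustment.
#' @param alpha significance level.
#' @param preprocess denoise the series before connectivity.
#' @param nodal compute nodal metric curves (disable for global-only
#'   runs at scale).
#' @param seed master seed.
#' @return Validated list of class `dmn_run_config`.
#' @export
run_config <- function(grid = sparsity_grid(), n_random = 1000,
                       swaps_per_edge = 100, edge_rank = c("signed", "abs"),
                       covariates = c("age", "BMI", "education"),
                       alpha = 0.05, preprocess = TRUE, nodal = TRUE,
                       seed = 1L) {
  edge_rank <- match.arg(edge_rank)
  stopifnot(all(diff(grid) > 0), all(grid > 0 & grid <= 1),
            n_random >= 0, swaps_per_edge >= 0, alpha > 0, alpha < 1)
  structure(list(grid = grid, n_random = n_random,
                 swaps_per_edge = swaps_per_edge, edge_rank = edge_rank,
                 covariates = covariates, alpha = alpha,
                 preprocess = preprocess, nodal = nodal,
                 seed = as.integer(seed)),
            class = "dmn_run_config")
}

#' Read / write a run configuration file
#'
#' Configurations serialize as JSON (default) or YAML, chosen by file
#' extension (`.yaml`/`.yml` requires the yaml package). Unknown fields
#' in the file are rejected by the [run_config()] validator.
#'
#' @param path configuration file.
#' @return `read_run_config`: a validated `dmn_run_config`;
#'   `write_run_config`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  is_yaml <- grepl("\\.ya?ml$", path, ignore.case = TRUE)
  raw <- if (is_yaml) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

#' @param config a [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "dmn_run_config"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration requires the yaml package")
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Per-subject connectivity and metric summaries
#'
#' Motion QC, optional denoising, Pearson connectivity, metric curves
#' over the sparsity grid, and AUC reduction for a whole cohort.
#'
#' @param cohort a `dmn_cohort` from [simulate_cohort()], or a list
#'   with `subjects`, `series`, and optional `motion`/`nuisance`
#'   elements (e.g. from [read_cohort()]).
#' @param config a [run_config()].
#' @return List: `qc` (QC report), `subjects` (included subjects),
#'   `fc` (list of connectivity matrices), `global_auc` and
#'   `nodal_auc` (long data frames), `component_curves` (largest
#'   component size per subject and sparsity).
#' @export
cohort_metrics <- function(cohort, config = run_config()) {
  subjects <- cohort$subjects
  tr <- cohort$tr %||% 2
  qc <- if (!is.null(cohort$motion)) motion_qc_report(cohort$motion) else NULL
  if (!is.null(qc)) {
    keep <- qc$decision == "include"
    if (any(!keep))
      message("motion QC excluded ", sum(!keep), " subject(s): ",
              paste(qc$subject_id[!keep], collapse = ", "))
    subjects <- subjects[subjects$subject_id %in% qc$subject_id[keep], ]
  }
  ids <- subjects$subject_id
  fc <- vector("list", length(ids)); names(fc) <- ids
  global_rows <- nodal_rows <- comp_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    x <- cohort$series[[id]]
    if (isTRUE(config$preprocess))
      x <- preprocess_timeseries(x, tr = tr,
                                 motion = cohort$motion[[id]],
                                 nuisance = cohort$nuisance[[id]])
    fc[[id]] <- fc_matrix(x)
    curves <- metric_curves(fc[[id]], grid = config$grid,
                            n_random = config$n_random,
                            swaps_per_edge = config$swaps_per_edge,
                            seed = derive_seed(config$seed, i),
                            rank = config$edge_rank,
                            nodal = isTRUE(config$nodal))
    sm <- auc_summary(curves)
    sm$global$subject_id <- id
    global_rows[[i]] <- sm$global
    if (!is.null(sm$nodal)) {
      sm$nodal$subject_id <- id
      nodal_rows[[i]] <- sm$nodal
    }
    comp <- curves$global[curves$global$metric == "largest_component", ]
    comp_rows[[i]] <- data.frame(subject_id = id, sparsity = comp$sparsity,
                                 size = comp$value, stringsAsFactors = FALSE)
  }
  list(qc = qc, subjects = subjects, fc = fc,
       global_auc = do.call(rbind, global_rows),
       nodal_auc = if (length(Filter(Negate(is.null), nodal_rows)))
         do.call(rbind, nodal_rows) else NULL,
       component_curves = do.call(rbind, comp_rows))
}

#' End-to-end two-group analysis
#'
#' Runs the full pipeline on a cohort: QC + denoising + connectivity +
#' topology ([cohort_metrics()]), then covariate-adjusted group
#' comparisons of global metric AUCs, edgewise connectivity and nodal
#' metric AUCs, the abnormal-connectivity composite score over the
#' significant edges, and Pearson correlations of that composite (and
#' the clustering-coefficient AUC) with clinical indices and global
#' topology within the case group.
#'
#' @param cohort a `dmn_cohort` (or compatible list).
#' @param config a [run_config()].
#' @param clinical_vars clinical columns of `subjects` to correlate.
#' @return List of class `dmn_report`: `metrics`, `global_comparison`,
#'   `edgewise`, `nodal`, `significant_edges`, `composite` (per-subject
#'   scores), `correlations`, `config`.
#' @export
analyze_cohort <- function(cohort, config = run_config(),
                           clinical_vars = c("AHI", "nadir_SaO2", "MoCA",
                                             "delayed_memory", "ESS")) {
  met <- cohort_metrics(cohort, config)
  subjects <- met$subjects
  glob <- compare_groups_metric(met$global_auc, subjects,
                                covariates = config$covariates)
  edge <- compare_edgewise(met$fc, subjects, covariates = config$covariates,
                           alpha = config$alpha)
  nodal <- if (!is.null(met$nodal_auc))
    compare_nodal(met$nodal_auc, subjects,
                  covariates = config$covariates, alpha = config$alpha)
  sig_edges <- edge[edge$significant, c("region1", "region2")]

  composite <- NULL
  correlations <- NULL
  if (nrow(sig_edges) > 0) {
    composite <- data.frame(
      subject_id = subjects$subject_id,
      group = subjects$group,
      score = vapply(met$fc[subjects$subject_id], abnormal_fc_score,
                     numeric(1), edges = sig_edges),
      stringsAsFactors = FALSE)
    case_level <- unique(subjects$group)[1]
    in_case <- composite$group == case_level
    case_ids <- composite$subject_id[in_case]
    ga <- met$global_auc
    corr_rows <- list()
    for (m in c("cp", "lp", "eglob", "eloc", "sigma")) {
      vals <- ga$auc[ga$metric == m][match(case_ids,
                ga$subject_id[ga$metric == m])]
      if (all(!is.finite(vals))) next
      ct <- tryCatch(correlate_clinical(composite$score[in_case], vals),
                     error = function(e) NULL)
      if (!is.null(ct))
        corr_rows[[length(corr_rows) + 1]] <- data.frame(
          x = "abnormal_fc", y = paste0(m, "_auc"), r = ct$r, p = ct$p,
          n = ct$n, stringsAsFactors = FALSE)
    }
    cp_auc <- ga$auc[ga$metric == "cp"][match(case_ids,
                ga$subject_id[ga$metric == "cp"])]
    for (v in intersect(clinical_vars, names(subjects))) {
      cv <- subjects[[v]][match(case_ids, subjects$subject_id)]
      for (pair in list(c("abnormal_fc", v), c("cp_auc", v))) {
        xvals <- if (pair[1] == "abnormal_fc") composite$score[in_case] else cp_auc
        ct <- tryCatch(correlate_clinical(xvals, cv), error = function(e) NULL)
        if (!is.null(ct))
          corr_rows[[length(corr_rows) + 1]] <- data.frame(
            x = pair[1], y = pair[2], r = ct$r, p = ct$p, n = ct$n,
            stringsAsFactors = FALSE)
      }
    }
    correlations <- do.call(rbind, corr_rows)
  }

  structure(list(metrics = met, global_comparison = glob, edgewise = edge,
                 nodal = nodal, significant_edges = sig_edges,
                 composite = composite, correlations = correlations,
                 config = config),
            class = "dmn_report")
}

#' Write an analysis report to disk
#'
#' Emits the group tables (global, edgewise, nodal), per-subject AUCs,
#' largest-component curves, composite scores and correlations as CSV,
#' the QC report, and a serialized copy of the run configuration.
#' Sections absent from `report` are recorded in `MISSING.txt` rather
#' than silently skipped.
#'
#' @param report a `dmn_report` from [analyze_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dmn_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  sections <- list(
    global_comparison = report$global_comparison,
    edgewise = report$edgewise,
    nodal = report$nodal,
    composite_scores = report$composite,
    correlations = report$correlations,
    global_auc = report$metrics$global_auc,
    nodal_auc = report$metrics$nodal_auc,
    component_curves = report$metrics$component_curves,
    qc = report$metrics$qc
  )
  missing_sections <- character(0)
  for (nm in names(sections)) {
    if (is.null(sections[[nm]])) {
      missing_sections <- c(missing_sections, nm)
    } else {
      write.csv(sections[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  if (length(missing_sections))
    writeLines(paste("MISSING:", missing_sections),
               file.path(dir, "MISSING.txt"))
  invisible(dir)
}
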