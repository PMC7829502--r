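## End-to-end orchestration: QC -> dynamic graphs -> partition ensembles
## -> metrics -> group statistics -> discrimination.

#' Pipeline run configuration
#'
#' @param window_length,window_step sliding window in volumes (TR units).
#' @param tr repetition time, seconds.
#' @param gamma,omega multilayer modularity parameters.
#' @param n_runs optimization restarts per subject.
#' @param seed master seed; all subject- and run-level seeds derive from
#'   it by a fixed counter scheme.
#' @param k features per fold for the classifier.
#' @param kernel SVM kernel ("radial" or "linear").
#' @param n_perm label permutations for classifier significance.
#' @param synthetic either NULL (real input) or a list with
#'   \code{n_per_group}, \code{design}, \code{effects} for the generator.
#' @param manifest,atlas_path real-data inputs (manifest TSV and atlas
#'   TSV paths); ignored when \code{synthetic} is given.
#' @return a \code{run_config} list, serialized verbatim into every
#'   output directory.
#' @export
run_config <- function(window_length = 20L, window_step = 20L, tr = 2.5,
                       gamma = 1, omega = 1, n_runs = 20L, seed = 1L,
                       k = 10L, kernel = "radial", n_perm = 200L,
                       synthetic = list(), manifest = NULL,
                       atlas_path = NULL) {
  structure(list(window_length = as.integer(window_length),
                 window_step = as.integer(window_step), tr = tr,
                 gamma = gamma, omega = omega, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), k = as.integer(k),
                 kernel = kernel, n_perm = as.integer(n_perm),
                 synthetic = synthetic, manifest = manifest,
                 atlas_path = atlas_path), class = "run_config")
}

#' Per-subject metric table from raw time series
#'
#' Convenience wrapper: sliding-window graph, multilayer assembly,
#' partition ensemble, metric table.
#'
#' @param subject a \code{subject_record} or node x volume matrix.
#' @param spec a \code{window_spec}.
#' @param params a \code{modularity_params}.
#' @param atlas optional \code{atlas} for network aggregation.
#' @return a \code{metric_table}.
#' @export
subject_metrics <- function(subject, spec, params, atlas = NULL) {
  dg <- dynamic_graph(subject, spec)
  mg <- build_multilayer(dg)
  ens <- partition_ensemble(mg, params)
  metric_table(ens, atlas)
}

#' Run the full pipeline
#'
#' Stages: motion QC (with exclusion), per-subject dynamic graphs and
#' partition ensembles, reconfiguration metrics, three-group comparisons
#' at network and node level, covariate-adjusted correlations with
#' cognitive scores in the patient groups, and MHE-vs-noHE LOOCV
#' discrimination on node disjointness with permutation significance.
#' Deterministic given \code{config$seed}.
#'
#' @param config a \code{run_config}.
#' @param atlas an \code{atlas}; defaults to the synthetic design's atlas
#'   or the configured atlas path.
#' @param out_dir optional directory; when given, every stage's artifacts
#'   are written there with the config as a JSON sidecar.
#' @param verbose print one status line per stage.
#' @return a \code{cohort_result} list: QC table, per-subject metric
#'   tables, group-comparison and correlation tables, and the
#'   classification result.
#' @export
run_pipeline <- function(config, atlas = NULL, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  ## stage 1: inputs
  if (length(config$synthetic)) {
    syn <- config$synthetic
    design <- syn$design %||% planted_design()
    effects <- syn$effects %||% cohort_effects(design$atlas)
    cohort <- generate_cohort(syn$n_per_group %||%
                                c(HC = 41L, noHE = 32L, MHE = 30L),
                              design, effects, seed = config$seed)
    subjects <- cohort$subjects
    if (is.null(atlas)) atlas <- design$atlas
    say("inputs: generated %d synthetic subjects", length(subjects))
  } else {
    cohort <- NULL
    if (is.null(atlas))
      atlas <- if (!is.null(config$atlas_path)) load_atlas(config$atlas_path)
               else power264_atlas()
    subjects <- load_subjects(config$manifest, atlas = atlas)
    say("inputs: loaded %d subjects", length(subjects))
  }

  ## stage 2: motion QC
  qc <- qc_cohort(subjects)
  keep <- !qc$excluded
  if (!all(keep))
    say("qc: excluded %d subject(s): %s", sum(!keep),
        paste(qc$subject_id[!keep], collapse = ", "))
  subjects <- subjects[keep]
  groups <- vapply(subjects, `[[`, character(1L), "group")

  ## stage 3-5: dynamic graphs, ensembles, metrics
  spec <- window_spec(config$window_length, config$window_step, config$tr)
  subj_seeds <- derive_seeds(config$seed, length(subjects))
  metrics <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    params <- modularity_params(config$gamma, config$omega, config$n_runs,
                                seed = subj_seeds[i])
    metrics[[i]] <- subject_metrics(subjects[[i]], spec, params, atlas)
  }
  say("metrics: %d subjects x %d runs", length(subjects), config$n_runs)

  node_names <- paste0("node", seq_len(atlas$n_nodes))
  disjoint <- t(vapply(metrics, `[[`, numeric(atlas$n_nodes),
                       "disjointness"))
  flex <- t(vapply(metrics, `[[`, numeric(atlas$n_nodes), "flexibility"))
  cohesion <- t(vapply(metrics, `[[`, numeric(atlas$n_nodes),
                       "cohesion_strength"))
  colnames(disjoint) <- colnames(flex) <- colnames(cohesion) <- node_names
  net_stab <- t(vapply(metrics, function(m)
    m$network_means$connection_stability,
    numeric(nrow(atlas$networks))))
  colnames(net_stab) <- atlas$networks$abbreviation
  net_disjoint <- t(vapply(metrics, function(m)
    m$network_means$disjointness, numeric(nrow(atlas$networks))))
  colnames(net_disjoint) <- atlas$networks$abbreviation

  ## stage 6: group statistics and correlations
  group_tests <- list(
    network_stability = compare_groups(net_stab, groups),
    network_disjointness = compare_groups(net_disjoint, groups),
    node_disjointness = compare_groups(disjoint, groups),
    node_flexibility = compare_groups(flex, groups),
    node_cohesion = compare_groups(cohesion, groups))
  say("group stats: %d families", length(group_tests))

  pat <- groups %in% c("noHE", "MHE")
  correlations <- NULL
  if (sum(pat) > 8L) {
    covar <- data.frame(
      age = vapply(subjects[pat], `[[`, numeric(1L), "age"),
      sex = vapply(subjects[pat], `[[`, character(1L), "sex"),
      education = vapply(subjects[pat], `[[`, numeric(1L), "education"),
      mean_fd = qc$mean_fd[keep][pat])
    if (anyNA(covar$mean_fd)) covar$mean_fd <- NULL
    if (length(unique(covar$sex)) < 2L) covar$sex <- NULL
    dst <- vapply(subjects[pat], `[[`, numeric(1L), "dst")
    nct <- vapply(subjects[pat], `[[`, numeric(1L), "nct_a")
    correlations <- list(
      network_stability_dst = correlate_units(net_stab[pat, , drop = FALSE],
                                              dst, covar),
      network_disjointness_dst = correlate_units(
        net_disjoint[pat, , drop = FALSE], dst, covar),
      network_disjointness_nct = correlate_units(
        net_disjoint[pat, , drop = FALSE], nct, covar))
  }

  ## stage 7: discrimination MHE vs noHE on node disjointness
  classification <- NULL
  if (sum(groups == "MHE") >= 3L && sum(groups == "noHE") >= 3L) {
    xm <- disjoint[pat, , drop = FALSE]
    ym <- groups[pat]
    classification <- permutation_test(xm, ym, k = config$k,
                                       n_perm = config$n_perm,
                                       seed = config$seed,
                                       kernel = config$kernel)
    say("classification: accuracy %.2f%%, permutation p %.4g",
        classification$observed, classification$p)
  }

  result <- structure(list(
    config = config, atlas = atlas, qc = qc, groups = groups,
    metrics = metrics, disjointness = disjoint, flexibility = flex,
    cohesion = cohesion, network_stability = net_stab,
    network_disjointness = net_disjoint, group_tests = group_tests,
    correlations = correlations, classification = classification,
    truth = if (!is.null(cohort)) cohort$truth[keep],
    effects = if (!is.null(cohort)) cohort$effects,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "cohort_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$config[!vapply(result$config, is.null,
                                             logical(1L))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write.table(result$qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in c("disjointness", "flexibility", "cohesion",
               "network_stability"))
    write.table(result[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(result$group_tests))
    write.table(result$group_tests[[nm]],
                file.path(out_dir, paste0("group_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$correlations))
    for (nm in names(result$correlations))
      write.table(result$correlations[[nm]],
                  file.path(out_dir, paste0("corr_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$classification)) {
    cl <- result$classification
    jsonlite::write_json(list(
      accuracy = cl$result$accuracy, sensitivity = cl$result$sensitivity,
      specificity = cl$result$specificity, auc = cl$result$auc,
      permutation_p = cl$p,
      consensus_features = cl$result$consensus_features),
      file.path(out_dir, "classification.json"), auto_unbox = TRUE,
      digits = NA)
    write.table(cl$result$roc, file.path(out_dir, "roc_points.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' @param x a \code{cohort_result} or a result directory written by
#'   \code{\link{run_pipeline}}.
#' @return character vector of markdown lines.
#' @export
pipeline_report <- function(x) {
  if (is.character(x)) return(report_from_dir(x))
  lines <- c("# Pipeline summary", "",
             sprintf("Subjects: %d (%s); excluded by QC: %d", length(x$groups),
                     paste(sprintf("%s=%d", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "),
                     sum(x$qc$excluded)),
             sprintf("Window %d TR step %d TR; gamma %.2f omega %.2f; %d runs",
                     x$config$window_length, x$config$window_step,
                     x$config$gamma, x$config$omega, x$config$n_runs), "")
  sig <- x$group_tests$node_disjointness
  sig <- sig$unit[sig$p_fdr < 0.05]
  lines <- c(lines, sprintf(
    "FDR-significant node-disjointness units (p_fdr < 0.05): %s",
    if (length(sig)) paste(sig, collapse = ", ") else "none"), "")
  if (!is.null(x$classification))
    lines <- c(lines, "## MHE vs noHE discrimination", "", sprintf(
      "accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f, permutation p %.4g",
      x$classification$result$accuracy, x$classification$result$sensitivity,
      x$classification$result$specificity, x$classification$result$auc,
      x$classification$p))
  lines
}

report_from_dir <- function(dir) {
  lines <- c("# Pipeline summary", "")
  cfg <- file.path(dir, "config.json")
  if (file.exists(cfg)) {
    cf <- jsonlite::read_json(cfg)
    lines <- c(lines, sprintf(
      "Config: window %s TR step %s TR, gamma %s omega %s, %s runs, seed %s",
      cf$window_length, cf$window_step, cf$gamma, cf$omega, cf$n_runs,
      cf$seed), "")
  } else {
    lines <- c(lines, "WARNING: no config.json found; incomplete run", "")
  }
  cls <- file.path(dir, "classification.json")
  if (file.exists(cls)) {
    cl <- jsonlite::read_json(cls)
    lines <- c(lines, sprintf(
      "Classification: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f, p %.4g",
      cl$accuracy, cl$sensitivity, cl$specificity, cl$auc,
      cl$permutation_p))
  } else {
    lines <- c(lines, "WARNING: no classification results found")
  }
  lines
}

#' Sweep windows and modularity parameters
#'
#' Re-runs the pipeline over a grid of window lengths and (gamma, omega)
#' pairs, collecting the classification accuracy per cell.
#'
#' @param config base \code{run_config}.
#' @param windows vector of window lengths (TR).
#' @param gammas,omegas parameter grids.
#' @param ... passed to \code{\link{run_pipeline}}.
#' @return data frame with one row per grid cell.
#' @export
pipeline_grid <- function(config, windows = config$window_length,
                          gammas = config$gamma, omegas = config$omega,
                          ...) {
  cells <- expand.grid(window = windows, gamma = gammas, omega = omegas)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$window_length <- as.integer(cells$window[i])
    cfg$gamma <- cells$gamma[i]; cfg$omega <- cells$omega[i]
    res <- run_pipeline(cfg, ...)
    data.frame(window = cells$window[i], gamma = cells$gamma[i],
               omega = cells$omega[i],
               accuracy = if (is.null(res$classification)) NA_real_
                          else res$classification$result$accuracy)
  })
  do.call(rbind, rows)
}
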