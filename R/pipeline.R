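#' Run one classification experiment end to end
#'
#' Executes the full pipeline for one technique and one task on a spectra set:
#' quality control (PCA / 95% Hotelling T2 per species, on the chain's
#' pre-scaling output), optional balanced subsampling for the species task,
#' a Q2-versus-complexity scan with the chosen validation scheme, and — at the
#' flagged optimum complexity — pooled ROC, the per-split AUC distribution and
#' the first-loading stability table. Identical config (including seed) gives
#' identical results.
#'
#' @param set a `spectra_set` with the task's label column, or `NULL` to
#'   generate the technique's synthetic set from [generate_coffee_suite()].
#' @param task `"species"` (balanced subsample applied) or `"origin"`
#'   (restricted to the Arabica samples, Colombia vs Other).
#' @param family `"plsda"` or `"oplsda"`.
#' @param chain preprocessing chain; default per technique.
#' @param scheme `"kfold"` or `"monte_carlo"`.
#' @param k folds for k-fold.
#' @param n_models,test_fraction Monte Carlo parameters.
#' @param k_max complexity scan range.
#' @param qc_level Hotelling confidence level.
#' @param seed integer seed driving QC-independent randomness (splits,
#'   subsampling).
#' @param technique used only when `set = NULL`.
#' @param out_dir optional directory; if given, all result tables plus a YAML
#'   manifest are written there as delimited text.
#' @return object of class `experiment_bundle`: list with `task`, `technique`,
#'   `family`, `qc` (report + counts), `curve`, `best_ncomp`, `validation`,
#'   `roc`, `aucs`, `stability`, `seed`, `n_before`, `n_after`.
#' @export
run_experiment <- function(set = NULL, task = c("species", "origin"),
                           family = c("oplsda", "plsda"),
                           chain = NULL, scheme = c("kfold", "monte_carlo"),
                           k = 7L, n_models = 100L, test_fraction = 1 / 7,
                           k_max = 4L, qc_level = 0.95, seed = 1L,
                           technique = "NMR", out_dir = NULL) {
  task <- match.arg(task)
  family <- match.arg(family)
  scheme <- match.arg(scheme)
  if (is.null(set)) {
    set <- generate_coffee_suite(seed = seed)[[technique]]
  }
  technique <- set$technique
  chain <- chain %||% default_chain(technique)
  if (task == "origin" && !"origin" %in% names(set$labels)) {
    abort_bad_arg("origin task requested but the set has no 'origin' label")
  }
  if (task == "origin" && !any(set$labels$origin == "Colombia")) {
    abort_bad_arg("origin task requested but no sample is labelled 'Colombia'")
  }

  # QC on the chain output before supervised/scaling steps, per species
  qcc <- fit_chain(qc_chain(chain), set)
  qc_group <- if ("species" %in% names(set$labels)) "species" else NULL
  qc <- reject_outliers(qcc$train, group_by = qc_group, level = qc_level)
  keep_ids <- qc$report$sample_id[!qc$report$rejected]
  clean <- subset_samples(set, keep_ids)

  if (task == "species") {
    lab_col <- "species"
    counts <- table(clean$labels$species)
    idx <- balanced_subsample(clean$labels$species, min(counts), seed = seed)
    work <- subset_samples(clean, idx)
    positive <- "Arabica"
  } else {
    lab_col <- "origin"
    work <- subset_samples(clean, clean$labels$species == "Arabica")
    positive <- "Colombia"
  }

  plan <- if (scheme == "kfold") {
    stratified_kfold(work$labels[[lab_col]], k = k, seed = seed)
  } else {
    monte_carlo_splits(work$labels[[lab_col]], n_models = n_models,
                       test_fraction = test_fraction, seed = seed)
  }
  curve <- component_curve(work, lab_col, family = family, k_max = k_max,
                           chain = chain, plan = plan, positive = positive)
  best <- curve$ncomp[curve$optimum]
  vr <- run_validation(work, lab_col, chain = chain, family = family,
                       ncomp = best, plan = plan, positive = positive)
  roc <- pooled_roc(vr)
  aucs <- suppressWarnings(auc_distribution(vr))
  stab <- loadings_stability(vr)

  bundle <- structure(list(
    task = task, technique = technique, family = family, scheme = scheme,
    qc = qc$report, n_before = n_samples(set), n_after = length(keep_ids),
    n_modelled = n_samples(work), curve = curve, best_ncomp = best,
    validation = vr, roc = roc, aucs = aucs, stability = stab, seed = seed
  ), class = "experiment_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.experiment_bundle <- function(x, ...) {
  g <- glance(x$validation)
  cat(sprintf("<experiment_bundle> %s / %s (%s, %s)\n", x$technique, x$task,
              x$family, x$scheme))
  cat(sprintf("  QC: %d -> %d samples; modelled: %d\n", x$n_before, x$n_after,
              x$n_modelled))
  cat(sprintf("  optimum complexity %d: mean Q2 = %.3f, pooled AUC = %.3f, accuracy = %.1f%%\n",
              x$best_ncomp, g$q2_mean, x$roc$auc, 100 * g$accuracy))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(bundle$qc, "qc_report")
  wr(bundle$curve, "component_curve")
  wr(bundle$validation$predictions, "predictions")
  wr(bundle$validation$q2, "q2_per_split")
  wr(bundle$roc$curve, "roc_curve")
  wr(bundle$aucs, "auc_per_split")
  wr(bundle$stability, "loading_stability")
  yaml::write_yaml(list(
    task = bundle$task, technique = bundle$technique, family = bundle$family,
    scheme = bundle$scheme, seed = bundle$seed, best_ncomp = bundle$best_ncomp,
    n_before_qc = bundle$n_before, n_after_qc = bundle$n_after,
    n_modelled = bundle$n_modelled, pooled_auc = bundle$roc$auc
  ), file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Compare techniques on the same task
#'
#' Summarises a list of experiment bundles (same task, different techniques)
#' into one table — optimum complexity, mean Q2 there, pooled AUC and AUC
#' quartiles — ranked by pooled AUC.
#'
#' @param bundles list of `experiment_bundle`s from the same task.
#' @return a tibble, one row per bundle, ordered best-first with a `rank`
#'   column (single-bundle input gets no rank).
#' @export
compare_techniques <- function(bundles) {
  if (inherits(bundles, "experiment_bundle")) bundles <- list(bundles)
  tasks <- unique(vapply(bundles, `[[`, character(1L), "task"))
  if (length(tasks) != 1L) {
    abort_bad_arg(sprintf("bundles mix tasks: %s", paste(tasks, collapse = ", ")))
  }
  tab <- purrr::map_dfr(bundles, function(b) {
    qs <- attr(b$aucs, "quartiles")
    g <- glance(b$validation)
    tibble::tibble(
      technique = b$technique, task = b$task, family = b$family,
      best_ncomp = b$best_ncomp, q2_mean = g$q2_mean, q2_sd = g$q2_sd,
      accuracy = g$accuracy, pooled_auc = b$roc$auc,
      auc_q1 = qs[[1L]], auc_median = qs[[2L]], auc_q3 = qs[[3L]]
    )
  })
  tab <- dplyr::arrange(tab, dplyr::desc(.data$pooled_auc))
  if (nrow(tab) > 1L) tab$rank <- seq_len(nrow(tab))
  tab
}
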