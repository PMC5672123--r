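#' Principal component analysis for quality checking
#'
#' Thin wrapper around [stats::prcomp()] (column-centered, unscaled) with a
#' fixed sign convention: each loading's largest-magnitude entry is positive.
#'
#' @param x numeric matrix (samples x variables) or `spectra_set`.
#' @param k number of components, `k <= min(n_samples - 1, n_vars)`.
#' @return object of class `pca_model`: `means`, orthonormal `loadings`
#'   (variables x k), `scores` (samples x k), `explained_variance` (score
#'   variances, non-increasing) and `total_variance`.
#' @export
fit_pca <- function(x, k = 2L) {
  if (inherits(x, "spectra_set")) x <- x$x
  n <- nrow(x)
  if (n < 2L) abort_bad_arg("PCA needs at least 2 samples")
  k <- as.integer(k)
  kmax <- min(n - 1L, ncol(x))
  if (k < 1L || k > kmax) {
    abort_bad_arg(sprintf("`k` must be in [1, %d] for a %d x %d matrix", kmax, n, ncol(x)))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(a) {
    v <- loadings[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  loadings <- sweep(loadings, 2L, flip, `*`)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, `*`)
  structure(list(
    means = pc$center, loadings = loadings, scores = scores,
    explained_variance = pc$sdev[seq_len(k)]^2,
    total_variance = sum(pc$sdev^2)
  ), class = "pca_model")
}

#' Hotelling's T-squared of each sample
#'
#' In the score space of the first `n_pcs` components:
#' `T2_i = sum_a t_ia^2 / lambda_a`, with `lambda_a` the score variance of
#' component `a`.
#'
#' @param model a `pca_model`.
#' @param n_pcs number of leading components (default 2).
#' @return numeric vector of non-negative per-sample statistics.
#' @export
hotelling_t2 <- function(model, n_pcs = 2L) {
  stopifnot(inherits(model, "pca_model"))
  if (n_pcs > ncol(model$scores)) abort_bad_arg("`n_pcs` exceeds the fitted components")
  lambda <- model$explained_variance[seq_len(n_pcs)]
  if (any(lambda <= 0)) abort_bad_arg("a leading component has zero variance")
  rowSums(sweep(model$scores[, seq_len(n_pcs), drop = FALSE]^2, 2L, lambda, `/`))
}

#' F-based Hotelling T-squared control limit
#'
#' The conventional chemometric ellipse limit:
#' `n_pcs * (n - 1) / (n - n_pcs) * F_level(n_pcs, n - n_pcs)`. For large `n`
#' it approaches the chi-square limit `qchisq(level, n_pcs)`.
#'
#' @param n training sample count, `n > n_pcs + 1`.
#' @param n_pcs number of components in the statistic.
#' @param level confidence level in (0, 1), default 0.95.
#' @return the critical value.
#' @export
t2_threshold <- function(n, n_pcs = 2L, level = 0.95) {
  if (n <= n_pcs + 1L) abort_bad_arg("`n` must exceed n_pcs + 1")
  if (level <= 0 || level >= 1) abort_bad_arg("`level` must be in (0, 1)")
  n_pcs * (n - 1) / (n - n_pcs) * stats::qf(level, n_pcs, n - n_pcs)
}

#' Reject outlying samples by the 95% Hotelling limit
#'
#' For each group (by default each species), a PCA is fitted on the group's
#' spectra and samples whose T-squared on the first two components exceeds the
#' F-based limit are removed, in a single pass (no re-fitting after removal).
#'
#' @param set a `spectra_set`, typically preprocessed up to (not including)
#'   autoscaling.
#' @param group_by label column defining the groups (default `"species"`; use
#'   `NULL` for a single group).
#' @param n_pcs,level statistic dimension and confidence level.
#' @return list with `set` (the retained samples) and `report`, a tibble
#'   (class `qc_report`) with one row per sample: `sample_id`, `group`, `t2`,
#'   `threshold`, `rejected`.
#' @export
reject_outliers <- function(set, group_by = "species", n_pcs = 2L, level = 0.95) {
  stopifnot(inherits(set, "spectra_set"))
  groups <- if (is.null(group_by)) rep("all", n_samples(set)) else {
    if (!group_by %in% names(set$labels)) {
      abort_bad_arg(sprintf("no label column '%s'", group_by))
    }
    as.character(set$labels[[group_by]])
  }
  report <- dplyr::bind_rows(lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < n_pcs + 2L) {
      abort_bad_arg(sprintf("group '%s' has %d samples; need > %d for T2 QC",
                            g, length(idx), n_pcs + 1L))
    }
    model <- fit_pca(set$x[idx, , drop = FALSE], k = n_pcs)
    t2 <- hotelling_t2(model, n_pcs)
    thr <- t2_threshold(length(idx), n_pcs, level)
    tibble::tibble(sample_id = rownames(set$x)[idx], group = g,
                   t2 = t2, threshold = thr, rejected = t2 > thr)
  }))
  report <- report[match(rownames(set$x), report$sample_id), ]
  class(report) <- c("qc_report", class(report))
  kept <- subset_samples(set, !report$rejected)
  list(set = kept, report = report)
}
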