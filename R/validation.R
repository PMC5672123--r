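#' Stratified k-fold split plan
#'
#' Within each class, samples are shuffled and dealt round-robin into `k`
#' folds, so every fold's class counts differ from proportional allocation by
#' at most one and the test folds partition the samples. Deterministic given
#' the seed.
#'
#' @param labels class label vector.
#' @param k number of folds (default 7).
#' @param seed integer seed.
#' @return object of class `split_plan`: a tibble with one row per split and
#'   list-columns `train` / `test` of integer indices.
#' @export
stratified_kfold <- function(labels, k = 7L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L || k > n) abort_bad_arg(sprintf("`k` must be in [2, %d]", n))
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    offset <- 0L # rotate the fold sequence across classes so fold sizes stay even
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  plan <- tibble::tibble(
    split = seq_len(k),
    train = lapply(seq_len(k), function(f) which(fold != f)),
    test = lapply(seq_len(k), function(f) which(fold == f))
  )
  new_split_plan(plan, scheme = "kfold", k = k, seed = seed, labels = labels)
}

#' Monte Carlo (repeated random stratified split) plan
#'
#' Draws `n_models` independent train/test splits; per class, the test set
#' takes `max(1, round(n_class * test_fraction))` samples, keeping the class
#' ratio within one sample of the full set's.
#'
#' @param labels class label vector.
#' @param n_models number of random splits (conventionally 100).
#' @param test_fraction fraction of each class assigned to the test set;
#'   default 1/7, matching 7-fold granularity.
#' @param seed integer seed.
#' @return a `split_plan`.
#' @export
monte_carlo_splits <- function(labels, n_models = 100L, test_fraction = 1 / 7,
                               seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  n_test <- vapply(classes, function(cl) {
    nc <- sum(labels == cl)
    nt <- max(1L, as.integer(round(nc * test_fraction)))
    if (nt >= nc) {
      abort_bad_arg(sprintf("test_fraction %.3g leaves no training samples for class '%s'",
                            test_fraction, cl))
    }
    nt
  }, integer(1L))
  splits <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_models), function(m) {
      test <- sort(unlist(lapply(classes, function(cl) {
        sample(which(labels == cl), n_test[[cl]])
      }), use.names = FALSE))
      list(train = setdiff(seq_along(labels), test), test = test)
    })
  })
  plan <- tibble::tibble(
    split = seq_len(n_models),
    train = lapply(splits, `[[`, "train"),
    test = lapply(splits, `[[`, "test")
  )
  new_split_plan(plan, scheme = "monte_carlo", n_models = n_models,
                 test_fraction = test_fraction, seed = seed, labels = labels)
}

new_split_plan <- function(plan, scheme, seed, labels, ...) {
  structure(plan, class = c("split_plan", class(plan)),
            scheme = scheme, seed = seed, labels = labels, extra = list(...))
}

#' Build a split plan from explicit index sets
#'
#' Escape hatch for custom validation designs, including the degenerate
#' resubstitution plan (`train = test = ` all samples), which downstream
#' results flag as non-validated.
#'
#' @param train,test lists of integer index vectors, one element per split.
#' @return a `split_plan`.
#' @export
split_plan <- function(train, test) {
  if (length(train) != length(test) || !length(train)) {
    abort_bad_arg("`train` and `test` must be non-empty lists of equal length")
  }
  plan <- tibble::tibble(split = seq_along(train), train = train, test = test)
  new_split_plan(plan, scheme = "manual", seed = NA_integer_, labels = NULL)
}

#' Balanced per-class subsample
#'
#' Draws exactly `per_class_n` samples from each class uniformly at random
#' (deterministic given the seed). Used to balance a species comparison, e.g.
#' drawing 19 of 66 Arabica against all 19 Robusta.
#'
#' @param labels class label vector.
#' @param per_class_n samples to keep per class; must not exceed the smallest
#'   class.
#' @param seed integer seed.
#' @return sorted integer index vector.
#' @export
balanced_subsample <- function(labels, per_class_n, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (per_class_n > min(counts)) {
    abort_bad_arg(sprintf("per_class_n = %d exceeds the smallest class (%d)",
                          per_class_n, min(counts)))
  }
  withr::with_seed(as.integer(seed), {
    sort(unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      idx[sample.int(length(idx), per_class_n)]
    }), use.names = FALSE))
  })
}

#' Cross-validated coefficient of prediction Q2
#'
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the mean taken
#' over the same (test) samples. 1 is perfect prediction, 0 matches the mean
#' predictor, negative values are worse than the mean.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return the statistic.
#' @export
q2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    abort_bad_arg("`observed` and `predicted` must have equal length >= 2")
  }
  tss <- sum((observed - mean(observed))^2)
  if (tss <= 0) abort_bad_arg("Q2 is undefined for constant `observed`")
  1 - sum((observed - predicted)^2) / tss
}

#' Run a cross-validated classification experiment
#'
#' For every split of the plan: the preprocessing chain is fitted on the
#' training partition only (scaler, MSC reference and OSC filter are
#' training-state), applied to the test partition, the classifier is fitted on
#' the transformed training data and its continuous scores collected on the
#' test data. Per-split Q2 values and the pooled prediction/observation
#' vectors are returned.
#'
#' @param set a `spectra_set` (typically after QC).
#' @param labels name of the label column defining the two classes.
#' @param chain a [preprocess_chain()]; defaults to the technique's
#'   [default_chain()].
#' @param family `"plsda"` or `"oplsda"`.
#' @param ncomp for `plsda`, the number of predictive components; for
#'   `oplsda`, `ncomp - 1` orthogonal components plus one predictive, so both
#'   families share a model-complexity axis starting at 1.
#' @param plan a `split_plan`; if `NULL`, a stratified k-fold plan is built.
#' @param k folds when `plan` is `NULL`.
#' @param seed seed for the default plan.
#' @param positive label coded +1.
#' @return object of class `validation_result`: list with `predictions`
#'   (tibble: split, sample_id, observed label, coded observation, predicted
#'   score), `q2` (tibble: split, q2), `models` (per-split fitted models),
#'   `plan`, and the class coding.
#' @export
run_validation <- function(set, labels, chain = default_chain(set$technique),
                           family = c("plsda", "oplsda"), ncomp = 2L,
                           plan = NULL, k = 7L, seed = 1L, positive = NULL) {
  stopifnot(inherits(set, "spectra_set"))
  family <- match.arg(family)
  lab <- set$labels[[labels]]
  if (is.null(lab)) abort_bad_arg(sprintf("no label column '%s'", labels))
  coding <- code_classes(lab, positive)
  if (is.null(plan)) plan <- stratified_kfold(lab, k = k, seed = seed)

  per_split <- purrr::map(seq_len(nrow(plan)), function(i) {
    tr <- plan$train[[i]]
    te <- plan$test[[i]]
    res <- tryCatch({
      train_set <- subset_samples(set, tr)
      test_set <- subset_samples(set, te)
      fc <- fit_chain(chain, train_set, y = coding$y[tr])
      model <- if (family == "plsda") {
        fit_plsda(fc$train, labels, ncomp = ncomp, positive = coding$positive)
      } else {
        fit_oplsda(fc$train, labels, n_orth = ncomp - 1L, positive = coding$positive)
      }
      test_proc <- apply_chain(fc$fitted, test_set)
      scores <- stats::predict(model, test_proc)
      list(model = model,
           pred = tibble::tibble(
             split = i, sample_id = rownames(test_set$x),
             observed_label = as.character(lab[te]),
             observed = coding$y[te], predicted = scores),
           q2 = if (length(te) >= 2L && stats::var(coding$y[te]) > 0) {
             q2(coding$y[te], scores)
           } else NA_real_)
    }, error = function(e) {
      rlang::abort(sprintf("split %d: %s", i, conditionMessage(e)), parent = e)
    })
    res
  })

  structure(list(
    predictions = dplyr::bind_rows(purrr::map(per_split, "pred")),
    q2 = tibble::tibble(split = plan$split,
                        q2 = vapply(per_split, `[[`, numeric(1L), "q2")),
    models = purrr::map(per_split, "model"),
    plan = plan, family = family, ncomp = ncomp,
    positive = coding$positive, negative = coding$negative,
    non_validated = any(vapply(seq_len(nrow(plan)), function(i) {
      length(intersect(plan$train[[i]], plan$test[[i]])) > 0
    }, logical(1L)))
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s, complexity %d: %d splits, mean Q2 = %.3f (sd %.3f)%s\n",
              x$family, x$ncomp, nrow(x$q2), mean(x$q2$q2, na.rm = TRUE),
              stats::sd(x$q2$q2, na.rm = TRUE),
              if (isTRUE(x$non_validated)) " [non-validated: train/test overlap]" else ""))
  invisible(x)
}

#' @rdname tidy.pls_model
#' @method tidy validation_result
#' @export
tidy.validation_result <- function(x, ...) x$q2

#' @rdname tidy.pls_model
#' @method glance validation_result
#' @export
glance.validation_result <- function(x, ...) {
  tibble::tibble(family = x$family, ncomp = x$ncomp, n_splits = nrow(x$q2),
                 q2_mean = mean(x$q2$q2, na.rm = TRUE),
                 q2_sd = stats::sd(x$q2$q2, na.rm = TRUE),
                 accuracy = mean((x$predictions$predicted > 0) ==
                                   (x$predictions$observed > 0)))
}

# ROC over continuous scores; ties handled by grouping equal thresholds
roc_points <- function(scores, is_pos) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- is_pos[ord]
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  grp_end <- which(!duplicated(s, fromLast = TRUE)) # last index of each tie group
  tibble::tibble(
    threshold = s[grp_end],
    tpr = cumsum(pos)[grp_end] / n_pos,
    fpr = cumsum(!pos)[grp_end] / n_neg
  )
}

#' Pooled ROC curve and AUC
#'
#' Concatenates the continuous test predictions of all splits into one vector
#' (and likewise the observations) and computes a single ROC curve over it;
#' the AUC is the trapezoidal integral, which equals the tie-corrected
#' Mann-Whitney concordance probability.
#'
#' @param result a `validation_result`, or a tibble/data.frame with columns
#'   `observed` (coded) and `predicted`.
#' @return object of class `roc_result`: `curve` tibble (threshold, fpr, tpr,
#'   starting from (0,0) and ending at (1,1)) and `auc`.
#' @export
pooled_roc <- function(result) {
  pr <- if (inherits(result, "validation_result")) result$predictions else result
  if (!nrow(pr)) abort_bad_arg("no pooled predictions")
  is_pos <- pr$observed > 0
  if (!any(is_pos) || all(is_pos)) abort_bad_arg("pooled predictions contain one class only")
  pts <- roc_points(pr$predicted, is_pos)
  curve <- dplyr::bind_rows(tibble::tibble(threshold = Inf, tpr = 0, fpr = 0), pts)
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(list(curve = curve, auc = auc,
                 n_pos = sum(is_pos), n_neg = sum(!is_pos)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname tidy.pls_model
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.pls_model
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Per-split AUC distribution
#'
#' One ROC AUC per split of the validation. Splits whose test set holds a
#' single class have no defined AUC; they are recorded as `NA` with a warning.
#'
#' @param result a `validation_result`.
#' @return tibble (split, auc) of class `auc_distribution`, with the quartile
#'   summary in `attr(, "quartiles")`.
#' @export
auc_distribution <- function(result) {
  stopifnot(inherits(result, "validation_result"))
  per <- result$predictions |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(auc = {
      obs <- .data$observed
      prd <- .data$predicted
      if (length(unique(obs > 0)) < 2L) NA_real_ else
        pooled_roc(tibble::tibble(observed = obs, predicted = prd))$auc
    }, .groups = "drop")
  if (anyNA(per$auc)) {
    warning(sprintf("%d split(s) had a single-class test set; AUC recorded as NA",
                    sum(is.na(per$auc))), call. = FALSE)
  }
  attr(per, "quartiles") <- stats::quantile(per$auc, c(0.25, 0.5, 0.75), na.rm = TRUE)
  class(per) <- c("auc_distribution", class(per))
  per
}

#' First-loading stability across splits
#'
#' Collects the first predictive loading of every split's model, sign-aligns
#' each to the first split (maximising the inner product), sorts variables by
#' decreasing mean absolute loading, and reports the relative error (standard
#' deviation / |mean|) per sorted position. Positions whose |mean| falls below
#' `1e-3` of the largest are flagged `noise_level`: small loadings near the
#' noise floor may vary wildly without affecting the discrimination.
#'
#' @param result a `validation_result` with at least 2 fitted models.
#' @return tibble of class `stability_result`: `position`, `axis`, `mean`,
#'   `sd`, `rel_error`, `noise_level`.
#' @export
loadings_stability <- function(result) {
  stopifnot(inherits(result, "validation_result"))
  if (length(result$models) < 2L) abort_bad_arg("need >= 2 fitted models")
  L <- lapply(result$models, first_loading)
  common <- Reduce(intersect, lapply(L, names))
  if (length(common) < 2L) abort_bad_arg("models share fewer than 2 variables")
  M <- do.call(rbind, lapply(L, function(v) v[common]))
  for (i in seq_len(nrow(M))[-1L]) {
    if (sum(M[i, ] * M[1L, ]) < 0) M[i, ] <- -M[i, ]
  }
  mu <- colMeans(M)
  sds <- col_sds(M)
  ord <- order(abs(mu), decreasing = TRUE)
  out <- tibble::tibble(
    position = seq_along(ord),
    axis = suppressWarnings(as.numeric(common[ord])),
    mean = mu[ord], sd = sds[ord],
    rel_error = ifelse(abs(mu[ord]) > 0, sds[ord] / abs(mu[ord]), NA_real_),
    noise_level = abs(mu[ord]) < 1e-3 * max(abs(mu))
  )
  class(out) <- c("stability_result", class(out))
  out
}

#' Q2 versus model complexity
#'
#' Fits and validates classifiers of increasing complexity `kk = 1..k_max`
#' (PLS-DA with `kk` predictive components, or oPLS-DA with one predictive and
#' `kk - 1` orthogonal components) and summarises the cross-validated Q2 per
#' complexity. The first local optimum of the mean-Q2 curve — the last `kk`
#' before the curve first drops — is flagged: beyond it the model overfits.
#'
#' @inheritParams run_validation
#' @param k_max largest complexity to scan.
#' @return tibble of class `component_curve`: `ncomp`, `q2_mean`, `q2_sd`,
#'   `optimum` (logical, exactly one TRUE).
#' @export
component_curve <- function(set, labels, family = c("plsda", "oplsda"),
                            k_max = 4L, chain = default_chain(set$technique),
                            plan = NULL, k = 7L, seed = 1L, positive = NULL) {
  family <- match.arg(family)
  if (k_max < 1L) abort_bad_arg("`k_max` must be >= 1")
  if (is.null(plan)) plan <- stratified_kfold(set$labels[[labels]], k = k, seed = seed)
  rows <- purrr::map_dfr(seq_len(k_max), function(kk) {
    vr <- run_validation(set, labels, chain = chain, family = family,
                         ncomp = kk, plan = plan, positive = positive)
    tibble::tibble(ncomp = kk, q2_mean = mean(vr$q2$q2, na.rm = TRUE),
                   q2_sd = stats::sd(vr$q2$q2, na.rm = TRUE))
  })
  opt <- which(diff(rows$q2_mean) < 0)
  opt <- if (length(opt)) opt[1L] else k_max
  rows$optimum <- seq_len(k_max) == opt
  class(rows) <- c("component_curve", class(rows))
  attr(rows, "family") <- family
  rows
}
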