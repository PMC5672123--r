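test_that("stratified k-fold keeps per-fold class counts within one of proportional", {
  labels <- rep(c("Colombia", "Other"), c(30, 36))
  plan <- stratified_kfold(labels, k = 7, seed = 4)
  col_per_fold <- vapply(plan$test, function(i) sum(labels[i] == "Colombia"),
                         integer(1))
  expect_true(all(col_per_fold %in% c(4L, 5L)))  # pigeonhole on 30/7
  # test folds partition the samples
  expect_setequal(unlist(plan$test), seq_along(labels))
  expect_equal(sum(lengths(plan$test)), length(labels))
  for (i in 1:7) expect_length(intersect(plan$train[[i]], plan$test[[i]]), 0)
  # determinism
  plan2 <- stratified_kfold(labels, k = 7, seed = 4)
  expect_identical(plan$test, plan2$test)
  expect_false(identical(plan$test, stratified_kfold(labels, k = 7, seed = 5)$test))
})

test_that("stratification property holds across schemes and seeds", {
  labels <- rep(c("a", "b"), c(22, 45))
  ratio <- 22 / 67
  for (seed in 1:5) {
    kf <- stratified_kfold(labels, k = 7, seed = seed)
    mc <- monte_carlo_splits(labels, n_models = 20, seed = seed)
    for (plan in list(kf, mc)) {
      for (i in seq_len(nrow(plan))) {
        tr <- plan$train[[i]]
        n_a <- sum(labels[tr] == "a")
        expect_lte(abs(n_a - ratio * length(tr)), 1 + 1e-9)
      }
    }
  }
})

test_that("leave-one-out degenerate k-fold yields singleton folds", {
  labels <- rep(c("a", "b"), each = 4)
  plan <- stratified_kfold(labels, k = 8, seed = 1)
  expect_true(all(lengths(plan$test) == 1L))
})

test_that("Monte Carlo plans have the requested size and coverage", {
  labels <- rep(c("a", "b"), c(47, 19))
  plan <- monte_carlo_splits(labels, n_models = 100, test_fraction = 1 / 7,
                             seed = 2)
  expect_equal(nrow(plan), 100L)
  a_test <- vapply(plan$test, function(i) sum(labels[i] == "a"), integer(1))
  b_test <- vapply(plan$test, function(i) sum(labels[i] == "b"), integer(1))
  expect_true(all(a_test == 7L) && all(b_test == 3L))
  # at 100 draws every sample appears in some test set with near certainty
  expect_setequal(unlist(plan$test), seq_along(labels))
  expect_error(monte_carlo_splits(labels, 10, test_fraction = 1e-4), NA)
  expect_error(monte_carlo_splits(rep(c("a", "b"), c(2, 60)), 10,
                                  test_fraction = 0.9), "training")
})

test_that("balanced subsampling draws exactly per_class_n from each class", {
  labels <- rep(c("Arabica", "Robusta"), c(66, 19))
  idx <- balanced_subsample(labels, 19, seed = 3)
  expect_length(idx, 38L)
  expect_equal(as.integer(table(labels[idx])), c(19L, 19L))
  # the limiting class is fully included
  expect_true(all(which(labels == "Robusta") %in% idx))
  expect_identical(idx, balanced_subsample(labels, 19, seed = 3))
  expect_error(balanced_subsample(labels, 20), "smallest")
})

test_that("Q2 closed-form cases", {
  obs <- c(1, -1, 1, -1)
  expect_equal(q2(obs, obs), 1)
  expect_equal(q2(obs, rep(mean(obs), 4)), 0)
  expect_equal(q2(obs, c(0.5, -0.5, 0.5, -0.5)), 0.75) # hand evaluation
  expect_lt(q2(obs, -obs), 0)       # worse than the mean predictor
  expect_lte(q2(obs, rnorm(4)), 1)  # never above 1
  expect_error(q2(c(1, 1), c(0, 0)), "constant")
  expect_error(q2(1, 1), "length")
})

test_that("pooled ROC matches brute-force concordance counting", {
  # hand case: positives {0.9, 0.4}, negatives {0.5, 0.1} -> 3 of 4 pairs
  pr <- tibble::tibble(observed = c(1, 1, -1, -1),
                       predicted = c(0.9, 0.4, 0.5, 0.1))
  expect_equal(pooled_roc(pr)$auc, 0.75)
  # perfect ordering and all-tied scores
  expect_equal(pooled_roc(tibble::tibble(observed = c(1, 1, -1),
                                         predicted = c(2, 3, 1)))$auc, 1)
  expect_equal(pooled_roc(tibble::tibble(observed = c(1, -1, 1, -1),
                                         predicted = rep(0.2, 4)))$auc, 0.5)
  expect_error(pooled_roc(tibble::tibble(observed = c(1, 1), predicted = 1:2)),
               "one class")
})

test_that("pooled AUC equals the normalised Mann-Whitney count with ties", {
  for (sd in 1:10) {
    withr::with_seed(sd, {
      obs <- sample(c(-1, 1), 40, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(obs)) < 2) obs[1:2] <- c(-1, 1)
      pred <- round(rnorm(40), 1) # coarse rounding forces ties
    })
    r <- pooled_roc(tibble::tibble(observed = obs, predicted = pred))
    pos <- pred[obs > 0]; neg <- pred[obs < 0]
    u <- sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg),
                    numeric(1)))
    expect_equal(r$auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
    # curve is a proper staircase from (0,0) to (1,1)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(utils::tail(r$curve$tpr, 1), 1)
    expect_equal(utils::tail(r$curve$fpr, 1), 1)
    expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))
  }
})

test_that("validation is leakage-safe and reproducible", {
  s <- generate_dataset(informative_config(seed = 44))
  vr1 <- run_validation(s, "class", family = "plsda", ncomp = 2, k = 7, seed = 9)
  vr2 <- run_validation(s, "class", family = "plsda", ncomp = 2, k = 7, seed = 9)
  expect_identical(vr1$predictions, vr2$predictions)
  # strong-signal set: every split predicts well
  expect_true(all(vr1$q2$q2 > 0.9, na.rm = TRUE))
  acc <- mean((vr1$predictions$predicted > 0) == (vr1$predictions$observed > 0))
  expect_equal(acc, 1)
})

test_that("permuted labels give mean Q2 at or below zero", {
  s <- generate_dataset(informative_config(seed = 50))
  q2s <- vapply(1:20, function(sd) {
    perm <- withr::with_seed(100 + sd, sample(nrow(s$labels)))
    s_perm <- s
    s_perm$labels$class <- s$labels$class[perm]
    vr <- run_validation(s_perm, "class", family = "plsda", ncomp = 2, k = 7,
                         seed = sd)
    mean(vr$q2$q2, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(q2s), 0)
})

test_that("a resubstitution plan is flagged as non-validated", {
  s <- generate_dataset(informative_config(seed = 52))
  n <- n_samples(s)
  plan <- split_plan(train = list(seq_len(n)), test = list(seq_len(n)))
  vr <- run_validation(s, "class", family = "plsda", ncomp = 1, plan = plan)
  expect_true(vr$non_validated)
  expect_equal(nrow(vr$predictions), n)
})

test_that("per-split AUC distribution covers each model and flags degenerate splits", {
  s <- generate_dataset(informative_config(seed = 60))
  plan <- monte_carlo_splits(s$labels$class, n_models = 25, seed = 1)
  vr <- run_validation(s, "class", family = "plsda", ncomp = 1, plan = plan)
  aucs <- auc_distribution(vr)
  expect_equal(nrow(aucs), 25L)
  expect_true(all(aucs$auc >= 0 & aucs$auc <= 1, na.rm = TRUE))
  expect_length(attr(aucs, "quartiles"), 3L)
  # separable data: all per-model AUCs are 1
  expect_true(all(aucs$auc == 1, na.rm = TRUE))

  # single-class test split -> NA with a warning
  plan2 <- split_plan(train = list(5:30, 5:30),
                      test = list(1:4, which(s$labels$class == "positive")[1:3]))
  vr2 <- run_validation(s, "class", family = "plsda", ncomp = 1, plan = plan2)
  expect_warning(a2 <- auc_distribution(vr2), "single-class")
  expect_true(is.na(a2$auc[2]))
})

test_that("loading stability is sign-aligned and tight for strong signals", {
  s <- generate_dataset(informative_config(seed = 70))
  vr <- run_validation(s, "class", family = "plsda", ncomp = 1, k = 7, seed = 2)
  st <- loadings_stability(vr)
  expect_equal(st$position, seq_len(nrow(st)))
  expect_true(all(diff(abs(st$mean)) <= 1e-12)) # sorted by decreasing |mean|
  top <- st[seq_len(ceiling(nrow(st) / 10)), ]
  expect_lt(max(top$rel_error), 0.10)

  # flipping a model's signs must not change the result
  vr_flip <- vr
  m <- vr_flip$models[[3]]
  m$x_loadings <- -m$x_loadings
  vr_flip$models[[3]] <- m
  st2 <- loadings_stability(vr_flip)
  expect_equal(st2$rel_error, st$rel_error, tolerance = 1e-12)
})

test_that("identical training sets give zero loading spread", {
  s <- generate_dataset(informative_config(seed = 72))
  n <- n_samples(s)
  plan <- split_plan(train = rep(list(1:20), 3), test = rep(list(21:n), 3))
  vr <- run_validation(s, "class", family = "plsda", ncomp = 1, plan = plan)
  st <- loadings_stability(vr)
  expect_equal(max(st$sd), 0, tolerance = 1e-12)
})

test_that("component curves peak then decline on overfittable data", {
  # weak class signal in many autoscaled variables: extra components chase
  # training noise and degrade the validated fit
  cfg <- synthetic_config(
    technique = "NIR", axis_lo = 4000, axis_hi = 6000, axis_step = 4,
    peaks = dplyr::bind_rows(peak_spec(4300, 30, 1),
                             peak_spec(5000, 30, 0.6, class_effect = 1.15),
                             peak_spec(5600, 40, 0.8)),
    n_per_class = c(12, 12), noise_sd = 0.25, scatter_slope_sd = 0.02,
    scatter_offset_sd = 0.01, baseline_amplitude = 0.01,
    confounder_amplitude = 0.2, seed = 80)
  s <- generate_dataset(cfg)
  chain <- preprocess_chain(list(list(step = "autoscale")))
  cc <- component_curve(s, "class", family = "plsda", k_max = 8, chain = chain,
                        k = 7, seed = 3)
  expect_equal(sum(cc$optimum), 1L)
  opt <- cc$ncomp[cc$optimum]
  expect_lt(opt, 8L)
  expect_equal(max(cc$q2_mean), cc$q2_mean[cc$ncomp == opt])
  expect_lt(cc$q2_mean[8], cc$q2_mean[cc$ncomp == opt]) # declines past the peak

  # training fit only improves with complexity (overfitting signature)
  n <- n_samples(s)
  resub <- split_plan(train = list(seq_len(n)), test = list(seq_len(n)))
  train_q2 <- vapply(1:8, function(kk) {
    vr <- run_validation(s, "class", chain = chain, family = "plsda",
                         ncomp = kk, plan = resub)
    vr$q2$q2[1]
  }, numeric(1))
  expect_true(all(diff(train_q2) >= -1e-8))
})

test_that("MC and k-fold validation agree on the same data", {
  s <- generate_dataset(informative_config(seed = 90,
                                           confounder_amplitude = 0.3))
  chain <- preprocess_chain(list(list(step = "autoscale")))
  kf <- run_validation(s, "class", chain = chain, family = "plsda", ncomp = 2,
                       k = 7, seed = 1)
  mc_plan <- monte_carlo_splits(s$labels$class, n_models = 100, seed = 1)
  mc <- run_validation(s, "class", chain = chain, family = "plsda", ncomp = 2,
                       plan = mc_plan)
  se <- sqrt(var(kf$q2$q2) / 7 + var(mc$q2$q2, na.rm = TRUE) / 100)
  expect_lt(abs(mean(kf$q2$q2) - mean(mc$q2$q2, na.rm = TRUE)), 2 * se + 1e-6)
})
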