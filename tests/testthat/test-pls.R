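# independent textbook NIPALS PLS1 oracle: plain loops, no shared code paths
nipals_oracle <- function(x, y, ncomp) {
  xm <- colMeans(x); ym <- mean(y)
  xc <- sweep(x, 2, xm); yc <- y - ym
  W <- P <- matrix(0, ncol(x), ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(t(xc) %*% yc); w <- w / sqrt(sum(w^2))
    t_a <- drop(xc %*% w)
    p_a <- drop(t(xc) %*% t_a) / sum(t_a^2)
    q[a] <- sum(yc * t_a) / sum(t_a^2)
    xc <- xc - outer(t_a, p_a)
    yc <- yc - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a
  }
  b <- W %*% solve(t(P) %*% W) %*% q
  list(b = drop(b), predict = function(newx) ym + drop(sweep(newx, 2, xm) %*% b))
}

test_that("a perfectly informative variable gives training correlation 1", {
  y <- rep(c(-1, 1), each = 6)
  x <- cbind(y, withr::with_seed(1, matrix(rnorm(36) * 0.01, 12, 3)))
  m <- fit_plsda(x, ifelse(y > 0, "pos", "neg"), ncomp = 1, positive = "pos")
  pred <- predict(m, x)
  expect_gt(cor(pred, y), 0.999)
  expect_gt(q2(y, pred), 0.99)
})

test_that("the first NIPALS weight is the normalised covariance direction", {
  x <- withr::with_seed(3, matrix(rnorm(10 * 6), 10, 6))
  lab <- rep(c("a", "b"), 5)
  m <- fit_plsda(x, lab, ncomp = 2)
  y <- ifelse(lab == "b", 1, -1)
  xc <- sweep(x, 2, colMeans(x)); yc <- y - mean(y)
  w1 <- drop(t(xc) %*% yc); w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(m$weights[, 1], w1, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fitted coefficients match an independent NIPALS implementation", {
  for (sd in c(5, 6)) {
    x <- withr::with_seed(sd, matrix(rnorm(8 * 5), 8, 5))
    lab <- rep(c("a", "b"), 4)
    y <- ifelse(lab == "b", 1, -1)
    m <- fit_plsda(x, lab, ncomp = 3)
    o <- nipals_oracle(x, y, 3)
    expect_equal(m$coefficients, o$b, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(predict(m, x), o$predict(x), tolerance = 1e-8)
  }
})

test_that("fitted loadings agree with mixOmics as an external cross-check", {
  x <- withr::with_seed(8, matrix(rnorm(12 * 7), 12, 7))
  lab <- rep(c("a", "b"), 6)
  y <- ifelse(lab == "b", 1, -1)
  m <- fit_plsda(x, lab, ncomp = 2)
  ext <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = FALSE)
  for (a in 1:2) {
    # mixOmics stores the unit projection (weight) vectors as loadings$X
    v <- unname(ext$loadings$X[, a])
    got <- unname(m$weights[, a])
    if (sum(got * v) < 0) v <- -v
    expect_equal(got, v, tolerance = 1e-6)
  }
})

test_that("model invariants: orthogonal scores, two prediction routes agree", {
  x <- withr::with_seed(10, matrix(rnorm(20 * 12), 20, 12))
  lab <- rep(c("a", "b"), 10)
  m <- fit_plsda(x, lab, ncomp = 4)
  g <- crossprod(m$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)

  # prediction via b equals prediction via sequential deflation
  newx <- withr::with_seed(11, matrix(rnorm(5 * 12), 5, 12))
  xc <- sweep(newx, 2, m$x_means)
  yhat <- rep(m$y_mean, 5)
  for (a in 1:4) {
    t_a <- drop(xc %*% m$weights[, a])
    yhat <- yhat + m$y_loadings[a] * t_a
    xc <- xc - outer(t_a, m$x_loadings[, a])
  }
  expect_equal(predict(m, newx), yhat, tolerance = 1e-10)
})

test_that("full-rank PLS reproduces the least-squares fit", {
  x <- withr::with_seed(12, matrix(rnorm(9 * 4), 9, 4))
  y <- withr::with_seed(13, rnorm(9))
  lab <- ifelse(y > median(y), "b", "a")
  yy <- ifelse(lab == "b", 1, -1)
  m <- fit_plsda(x, lab, ncomp = 4)
  ls <- lm.fit(cbind(1, x), yy)
  expect_equal(predict(m, x), unname(ls$fitted.values), tolerance = 1e-6)
})

test_that("scores are invariant under consistent variable permutation", {
  x <- withr::with_seed(14, matrix(rnorm(14 * 9), 14, 9))
  lab <- rep(c("a", "b"), 7)
  perm <- withr::with_seed(15, sample(9))
  m1 <- fit_plsda(x, lab, ncomp = 2)
  m2 <- fit_plsda(x[, perm], lab, ncomp = 2)
  expect_equal(m1$scores, m2$scores, tolerance = 1e-9)
  expect_equal(predict(m1, x), predict(m2, x[, perm]), tolerance = 1e-9)
})

test_that("errors: single class, rank overflow with the usable maximum named", {
  x <- withr::with_seed(16, matrix(rnorm(12), 6, 2))
  expect_error(fit_plsda(x, rep("a", 6), ncomp = 1), "two classes")
  expect_error(fit_plsda(x, rep(c("a", "b"), 3), ncomp = 5), "max usable")
})

test_that("oPLS with zero orthogonal components reduces to 1-component PLS", {
  x <- withr::with_seed(20, matrix(rnorm(16 * 10), 16, 10))
  lab <- rep(c("a", "b"), 8)
  newx <- withr::with_seed(21, matrix(rnorm(4 * 10), 4, 10))
  p1 <- predict(fit_plsda(x, lab, ncomp = 1), newx)
  p2 <- predict(fit_oplsda(x, lab, n_orth = 0), newx)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("oPLS orthogonal scores are orthogonal to the coded response", {
  x <- withr::with_seed(22, matrix(rnorm(20 * 15), 20, 15))
  lab <- rep(c("a", "b"), 10)
  m <- fit_oplsda(x, lab, n_orth = 3)
  y <- ifelse(lab == "b", 1, -1)
  for (j in 1:3) {
    t_o <- m$orth_scores[, j]
    expect_lt(abs(sum(t_o * y)) / (sqrt(sum(t_o^2)) * sqrt(sum(y^2))), 1e-8)
  }
})

test_that("oPLS concentrates class correlation when a confounder interferes", {
  wins <- vapply(1:20, function(sd) {
    withr::with_seed(sd, {
      y <- rep(c(-1, 1), each = 12)
      u <- rnorm(24); u <- u - y * sum(u * y) / sum(y^2)
      v1 <- rnorm(40); v2 <- rnorm(40)
      x <- tcrossprod(y, v1) + 4 * tcrossprod(u, v2) +
        matrix(rnorm(24 * 40, sd = 0.1), 24, 40)
    })
    lab <- ifelse(y > 0, "b", "a")
    pls1 <- fit_plsda(x, lab, ncomp = 1)
    opls <- fit_oplsda(x, lab, n_orth = 1)
    abs(cor(opls$scores, y)) > abs(cor(pls1$scores[, 1], y))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("classification maps the 0 threshold with ties to the negative class", {
  x <- withr::with_seed(30, matrix(rnorm(12 * 4), 12, 4))
  lab <- rep(c("a", "b"), 6)
  m <- fit_plsda(x, lab, ncomp = 1)
  got <- classify(m, x)
  expect_setequal(unique(got), c("a", "b"))
  expect_identical(got, ifelse(predict(m, x) > 0, "b", "a"))
  # force an exact-zero score by predicting the training means row
  zero_row <- matrix(m$x_means, 1)
  expect_equal(predict(m, zero_row), m$y_mean)
  if (abs(m$y_mean) < 1e-12) expect_identical(classify(m, zero_row), "a")
})

test_that("tidy and glance summarise fitted models", {
  s <- generate_dataset(informative_config(seed = 33))
  cx <- coded_xy(s)
  m <- fit_plsda(cx$set, "class", ncomp = 2, positive = "positive")
  td <- tidy(m)
  expect_named(td, c("component", "axis", "weight", "loading"))
  expect_equal(nrow(td), 2L * n_variables(cx$set))
  o <- fit_oplsda(cx$set, "class", n_orth = 1, positive = "positive")
  expect_setequal(unique(tidy(o)$component), c("predictive", "orthogonal1"))
  expect_equal(glance(m)$ncomp, 2L)
})
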