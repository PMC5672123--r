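test_that("region selection uses the half-open convention", {
  s <- tiny_set(2, 1500, axis = make_grid(4000, 10000, 4))
  sel <- select_region(s, 4000, 7600)
  expect_equal(n_variables(sel), 900L)
  expect_true(all(sel$axis >= 4000 & sel$axis < 7600))
  # whole-axis selection is the identity
  expect_identical(select_region(s, 4000, 10001)$x, s$x)
  expect_error(select_region(s, 10001, 10002), "no variables")
})

test_that("region removal is a set difference with union semantics", {
  s <- tiny_set(1, 11, axis = 0:10)
  expect_identical(remove_regions(s, list()), s)
  r <- remove_regions(s, list(c(3, 6)))
  expect_equal(r$axis, c(0, 1, 2, 6, 7, 8, 9, 10))
  expect_equal(r$x[1, ], s$x[1, c(1:3, 7:11)])
  r2 <- remove_regions(s, list(c(1, 4), c(3, 6)))
  expect_equal(r2$axis, remove_regions(s, list(c(1, 6)))$axis)
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives exactly", {
  axis <- seq(0, 10, by = 0.5)
  const <- spectra_set(matrix(3, 2, length(axis)), axis, "NIR")
  expect_equal(savitzky_golay(const, 7, 3, 0)$x, const$x, tolerance = 1e-12)

  quad <- spectra_set(unname(rbind(axis^2, 2 * axis^2 + axis)), axis, "NIR")
  d2 <- savitzky_golay(quad, 7, 3, 2)
  # second derivative of x^2 is exactly 2 everywhere, including edges
  expect_equal(d2$x[1, ], rep(2, length(axis)), tolerance = 1e-9)
  expect_equal(d2$x[2, ], rep(4, length(axis)), tolerance = 1e-9)
})

test_that("Savitzky-Golay matches a brute-force sliding polyfit oracle", {
  # oracle: fit a polynomial by least squares in each centered window and
  # differentiate it analytically at the center
  sg_oracle <- function(y, h, window, polyorder, deriv) {
    half <- (window - 1) / 2
    n <- length(y)
    vapply(seq_len(n), function(i) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      if (hi - lo + 1 < window) { lo <- max(1, hi - window + 1); hi <- min(n, lo + window - 1) }
      xs <- (seq(lo, hi) - i) * h
      fit <- lm.fit(outer(xs, 0:polyorder, `^`), y[lo:hi])
      factorial(deriv) * fit$coefficients[deriv + 1]
    }, numeric(1))
  }
  axis <- seq(100, 130, by = 1.5)
  y <- withr::with_seed(8, rnorm(length(axis)))
  s <- spectra_set(matrix(y, 2, length(axis), byrow = TRUE), axis, "NIR")
  for (params in list(c(9, 3, 1), c(7, 2, 0), c(11, 4, 2))) {
    got <- savitzky_golay(s, params[1], params[2], params[3])$x[1, ]
    want <- sg_oracle(y, 1.5, params[1], params[2], params[3])
    half <- (params[1] - 1) / 2
    interior <- (half + 1):(length(axis) - half)
    expect_equal(got[interior], unname(want[interior]), tolerance = 1e-10)
  }
})

test_that("Savitzky-Golay interpolation limit and argument contract", {
  axis <- 1:21
  y <- withr::with_seed(2, rnorm(21))
  s <- spectra_set(matrix(y, 1), axis, "NIR")
  # polyorder = window - 1 with deriv 0 reproduces the input
  expect_equal(savitzky_golay(s, 5, 4, 0)$x[1, ], y, tolerance = 1e-9)
  expect_error(savitzky_golay(s, 10, 3, 0), "odd.*9.*11")
  expect_error(savitzky_golay(s, 7, 7, 0), "polyorder")
  expect_error(savitzky_golay(s, 7, 3, 4), "deriv")
  expect_error(savitzky_golay(s, 23, 3, 0), "exceeds")
})

test_that("MSC inverts affine scatter distortion exactly", {
  axis <- seq(4000, 4400, by = 4)
  ref <- exp(-0.5 * ((axis - 4200) / 50)^2) + 0.3
  x <- unname(rbind(ref, 2 * ref + 3, 0.5 * ref - 1))
  s <- spectra_set(x, axis, "NIR")
  corrected <- msc(s, reference = ref)
  for (i in 1:3) expect_equal(corrected$x[i, ], unname(ref), tolerance = 1e-10)
})

test_that("MSC slope and intercept match the closed-form OLS oracle", {
  s <- tiny_set(5, 60, axis = seq(1, 60), seed = 9)
  ref <- colMeans(s$x)
  out <- msc(s, reference = "mean")
  for (i in 1:5) {
    r <- s$x[i, ]
    m_hat <- sum((r - mean(r)) * (ref - mean(ref))) / sum((ref - mean(ref))^2)
    b_hat <- mean(r) - m_hat * mean(ref)
    expect_equal(out$x[i, ], (r - b_hat) / m_hat, tolerance = 1e-10)
  }
  # idempotence against the same reference
  again <- msc(out, reference = ref)
  expect_equal(again$x, out$x, tolerance = 1e-10)
  expect_error(msc(s, reference = rep(1, 60)), "zero variance")
})

test_that("integral normalisation scales |sum| to the target and is idempotent", {
  s <- tiny_set(4, 30, seed = 3)
  out <- integral_normalize(s, 100)
  expect_equal(unname(rowSums(abs(out$x))), rep(100, 4), tolerance = 1e-9)
  expect_equal(integral_normalize(out, 100)$x, out$x, tolerance = 1e-12)
  z <- spectra_set(rbind(c(1, 2, 3), c(0, 0, 0)), 1:3, "ATR-mIR")
  expect_error(integral_normalize(z), "s2")
})

test_that("binning conserves totals and hits the standard 1100-point target", {
  dense <- spectra_set(matrix(withr::with_seed(5, rnorm(2 * 80501)), 2, 80501),
                       seq(0.5, 9.5, length.out = 80501), "NMR")
  b <- bin_uniform(dense, 1100)
  expect_equal(n_variables(b), 1100L)
  expect_equal(rowSums(b$x), rowSums(dense$x), tolerance = 1e-9)
  expect_length(attr(b, "empty_bins"), 0L)

  # constant spectrum: every bin holds its member count
  cs <- spectra_set(matrix(1, 1, 100), seq(0, 99), "NMR")
  expect_equal(unique(as.vector(bin_uniform(cs, 10)$x)), 10)
  # n_bins = n_vars conserves the total as well
  expect_equal(sum(bin_uniform(cs, 100)$x), 100)
  expect_error(bin_uniform(cs, 0), "n_bins")
  expect_error(bin_uniform(cs, 101), "exceeds")
})

test_that("autoscaler is train/test-safe and handles zero variance", {
  s <- tiny_set(6, 8, seed = 13)
  sc <- fit_autoscaler(s)
  z <- apply_autoscaler(sc, s)
  expect_lt(max(abs(colMeans(z$x))), 1e-12)
  expect_equal(unname(apply(z$x, 2, sd)), rep(1, 8), tolerance = 1e-12)

  # shifted test set: every entry moves by 1/sd per column (hand formula)
  shifted <- spectra_set(s$x + 1, s$axis, s$technique)
  zt <- apply_autoscaler(sc, shifted)
  expect_equal(zt$x, z$x + rep(1 / sc$sds, each = 6), tolerance = 1e-12)

  const <- spectra_set(matrix(5, 3, 4), 1:4, "NIR")
  expect_warning(sc0 <- fit_autoscaler(const), "zero-variance")
  expect_equal(sum(sc0$keep), 0L)
  one_zero <- spectra_set(cbind(c(1, 2, 3), c(7, 7, 7)), 1:2, "NIR")
  expect_warning(sc1 <- fit_autoscaler(one_zero), "2")
  expect_equal(n_variables(apply_autoscaler(sc1, one_zero)), 1L)
})

test_that("fitted chains replay their training state on new data", {
  cfg <- informative_config(seed = 17)
  s <- generate_dataset(cfg)
  chain <- preprocess_chain(list(
    list(step = "select_region", lo = 4000, hi = 4900),
    list(step = "savitzky_golay", window = 11L, polyorder = 3L, deriv = 2L),
    list(step = "msc"),
    list(step = "osc", n_components = 1L),
    list(step = "autoscale")
  ))
  y <- ifelse(s$labels$class == "positive", 1, -1)
  fc <- fit_chain(chain, s, y = y)
  # replaying on the training data reproduces the fit-time output
  expect_equal(apply_chain(fc$fitted, s)$x, fc$train$x, tolerance = 1e-10)
  # chains are deterministic
  fc2 <- fit_chain(chain, s, y = y)
  expect_identical(fc$train$x, fc2$train$x)
  expect_error(fit_chain(chain, s), "osc")
  expect_error(preprocess_chain(list(list(step = "nope"))), "unknown")
})
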