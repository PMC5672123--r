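# small fixtures built in code

# minimal valid set: n samples on a short uniform axis
tiny_set <- function(n = 3L, p = 5L, axis = seq_len(p), seed = 1L,
                     technique = "NIR", labels = NULL) {
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  spectra_set(x, axis, technique, labels = labels)
}

# quick two-class config with one informative peak and low noise
informative_config <- function(seed = 1L, ...) {
  synthetic_config(
    technique = "NIR", axis_lo = 4000, axis_hi = 5000, axis_step = 4,
    peaks = dplyr::bind_rows(
      peak_spec(4200, 40, 1.0),
      peak_spec(4600, 40, 0.8, class_effect = 2),
      peak_spec(4800, 50, 0.9)
    ),
    n_per_class = c(15, 15), noise_sd = 0.01, scatter_slope_sd = 0,
    scatter_offset_sd = 0, baseline_amplitude = 0, seed = seed, ...)
}

# autoscaled matrix + coded response from a generated set
coded_xy <- function(set, label_col = "class", positive = NULL) {
  sc <- fit_autoscaler(set)
  xs <- apply_autoscaler(sc, set)
  lab <- set$labels[[label_col]]
  lev <- sort(unique(lab))
  pos <- positive %||% lev[2]
  list(x = intensity_matrix(xs), y = ifelse(lab == pos, 1, -1), set = xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
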