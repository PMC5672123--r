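#' Build a uniform spectral axis
#'
#' The grid covers the half-open interval `[lo, hi)` with spacing `step`:
#' `length = floor((hi - lo) / step)`. This is the single interval convention
#' used by all region operations, and it reproduces the standard acquisition
#' grids, e.g. 4000-10000 cm^-1 at 4 cm^-1 gives 1500 points and its
#' 4000-7600 cm^-1 selection 900 points.
#'
#' @param lo,hi interval ends, `lo < hi`.
#' @param step positive spacing in axis units.
#' @return increasing numeric axis.
#' @export
make_grid <- function(lo, hi, step) {
  check_number(step, "step", lower = 0, strict = TRUE)
  if (!(lo < hi)) abort_bad_arg("`lo` must be < `hi`")
  n <- floor((hi - lo) / step + 1e-9)
  if (n < 1L) abort_bad_arg("grid would be empty")
  lo + step * (seq_len(n) - 1L)
}

#' Describe one synthetic peak
#'
#' @param center peak position in axis units.
#' @param width scale parameter (> 0): the Gaussian sd or Lorentzian half-width.
#' @param amplitude base height (>= 0).
#' @param class_effect multiplicative amplitude factor applied to
#'   positive-class samples; 1 means no class information.
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return one-row tibble; rows from several calls can be bound into a peak table.
#' @export
peak_spec <- function(center, width, amplitude, class_effect = 1, shape = "gaussian") {
  check_number(width, "width", lower = 0, strict = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(class_effect, "class_effect", lower = 0)
  shape <- match.arg(shape, c("gaussian", "lorentzian"))
  tibble::tibble(center = center, width = width, amplitude = amplitude,
                 class_effect = class_effect, shape = shape)
}

peak_profile <- function(axis, center, width, shape) {
  z <- (axis - center) / width
  if (shape == "lorentzian") 1 / (1 + z^2) else exp(-0.5 * z^2)
}

#' Full recipe for one synthetic dataset
#'
#' Encodes the generative model: per sample `i` of class `c`,
#' `s_i(x) = m_i * (sum_p a_p(c) f_p(x) + baseline_i(x) + u_i g(x)) + b_i + e_i(x)`
#' with `a_p(c) = amplitude_p * class_effect_p^[c = positive]`, multiplicative
#' scatter `m_i ~ 1 + N(0, scatter_slope_sd)`, additive offset
#' `b_i ~ N(0, scatter_offset_sd)`, a random cubic baseline with coefficients
#' `~ N(0, baseline_amplitude)`, a fixed structured confounder pattern `g`
#' loaded by `u_i ~ N(0, confounder_amplitude)` independent of class, and
#' i.i.d. noise `e ~ N(0, noise_sd)`. A fraction `outlier_fraction` of samples
#' has its whole spectrum multiplied by `outlier_scale`.
#'
#' @param technique technique tag.
#' @param axis_lo,axis_hi,axis_step grid definition per [make_grid()];
#'   alternatively give `n_points` for an inclusive `seq(axis_lo, axis_hi,
#'   length.out = n_points)` grid (used for dense NMR grids).
#' @param peaks tibble of [peak_spec()] rows.
#' @param n_per_class length-2 integer vector `(negative, positive)`.
#' @param class_labels length-2 character `(negative, positive)`.
#' @param scatter_slope_sd,scatter_offset_sd,baseline_amplitude,noise_sd,
#'   confounder_amplitude non-negative scales, see above.
#' @param outlier_fraction fraction in `[0, 0.5)`; `outlier_scale` the gross
#'   multiplier applied to planted outliers.
#' @param n_points optional inclusive-grid size (see above).
#' @param seed integer seed; the whole dataset is a pure function of the config.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(technique = "NIR",
                             axis_lo = 4000, axis_hi = 10000, axis_step = 4,
                             peaks = default_peaks(technique),
                             n_per_class = c(30, 30),
                             class_labels = c("negative", "positive"),
                             scatter_slope_sd = 0.05, scatter_offset_sd = 0.02,
                             baseline_amplitude = 0.02, noise_sd = 0.02,
                             confounder_amplitude = 0, outlier_fraction = 0,
                             outlier_scale = 5, n_points = NULL, seed = 1L) {
  for (nm in c("scatter_slope_sd", "scatter_offset_sd", "baseline_amplitude",
               "noise_sd", "confounder_amplitude")) {
    check_number(get(nm), nm, lower = 0)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    abort_bad_arg("`outlier_fraction` must be in [0, 0.5)")
  }
  if (!(axis_lo < axis_hi)) abort_bad_arg("`axis_lo` must be < `axis_hi`")
  if (any(n_per_class < 1)) abort_bad_arg("`n_per_class` must be >= 1 per class")
  structure(list(
    technique = technique, axis_lo = axis_lo, axis_hi = axis_hi,
    axis_step = axis_step, n_points = n_points, peaks = tibble::as_tibble(peaks),
    n_per_class = as.integer(n_per_class), class_labels = class_labels,
    scatter_slope_sd = scatter_slope_sd, scatter_offset_sd = scatter_offset_sd,
    baseline_amplitude = baseline_amplitude, noise_sd = noise_sd,
    confounder_amplitude = confounder_amplitude,
    outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# a small generic peak table so synthetic_config() works out of the box;
# class information sits on a handful of peaks, mirroring the few
# discriminating signals seen in real fingerprints
default_peaks <- function(technique) {
  if (identical(technique, "NMR")) {
    dplyr::bind_rows(
      peak_spec(1.2, 0.03, 1.0, shape = "lorentzian"),
      peak_spec(2.4, 0.03, 0.8, shape = "lorentzian"),
      peak_spec(3.9, 0.04, 0.9, shape = "lorentzian"),
      peak_spec(5.8, 0.02, 0.30, class_effect = 2.0, shape = "lorentzian"),
      peak_spec(6.2, 0.02, 0.25, class_effect = 2.0, shape = "lorentzian"),
      peak_spec(6.3, 0.02, 0.25, class_effect = 2.0, shape = "lorentzian"),
      peak_spec(7.3, 0.02, 0.30, class_effect = 2.0, shape = "lorentzian"),
      peak_spec(8.4, 0.03, 0.5, shape = "lorentzian")
    )
  } else {
    lo <- if (identical(technique, "ATR-mIR")) 800 else 4000
    hi <- if (identical(technique, "ATR-mIR")) 1800 else 7600
    span <- hi - lo
    dplyr::bind_rows(
      peak_spec(lo + 0.15 * span, 0.02 * span, 1.0),
      peak_spec(lo + 0.35 * span, 0.03 * span, 0.8),
      peak_spec(lo + 0.50 * span, 0.02 * span, 0.6, class_effect = 1.6),
      peak_spec(lo + 0.65 * span, 0.03 * span, 0.9),
      peak_spec(lo + 0.80 * span, 0.02 * span, 0.5, class_effect = 1.6)
    )
  }
}

config_axis <- function(config) {
  if (!is.null(config$n_points)) {
    seq(config$axis_lo, config$axis_hi, length.out = config$n_points)
  } else {
    make_grid(config$axis_lo, config$axis_hi, config$axis_step)
  }
}

# smooth fixed confounder pattern: three broad bumps spanning the axis,
# deterministic in the axis alone so train/test share it
confounder_pattern <- function(axis) {
  lo <- min(axis); span <- max(axis) - lo
  g <- peak_profile(axis, lo + 0.25 * span, 0.08 * span, "gaussian") -
    peak_profile(axis, lo + 0.55 * span, 0.10 * span, "gaussian") +
    peak_profile(axis, lo + 0.85 * span, 0.06 * span, "gaussian")
  g / max(abs(g))
}

# core simulator: amp is an n_samples x n_peaks amplitude matrix (class and
# origin effects already folded in); returns the intensity matrix plus the
# per-sample draws used, all under the caller's RNG state
simulate_spectra <- function(axis, peaks, amp, scatter_slope_sd, scatter_offset_sd,
                             baseline_amplitude, noise_sd, confounder_amplitude) {
  n <- nrow(amp)
  p <- length(axis)
  profiles <- vapply(seq_len(nrow(peaks)),
                     function(j) peak_profile(axis, peaks$center[j], peaks$width[j],
                                              peaks$shape[j]),
                     numeric(p)) # p x n_peaks
  signal <- amp %*% t(profiles) # n x p

  u <- stats::rnorm(n, 0, 1) * confounder_amplitude
  m <- 1 + stats::rnorm(n, 0, scatter_slope_sd)
  b <- stats::rnorm(n, 0, scatter_offset_sd)
  xg <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  basis <- cbind(1, xg, xg^2, xg^3)
  coefs <- matrix(stats::rnorm(4L * n, 0, baseline_amplitude), n, 4L)
  baseline <- coefs %*% t(basis)

  g <- confounder_pattern(axis)
  x <- m * (signal + baseline + tcrossprod(u, g)) + b +
    matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  list(x = x, u = u, m = m, b = b)
}

#' Generate one synthetic spectra set
#'
#' Realises the generative model recorded in a [synthetic_config()]. The
#' output carries a planted-truth table (`attr(, "truth")`): per-sample class,
#' confounder loading and outlier flag, plus the class-effect peak centers in
#' `attr(, "class_peaks")`. Identical config (including seed) gives
#' bit-identical output; the global RNG state is left untouched.
#'
#' @param config a `synthetic_config`.
#' @param seed optional override of `config$seed`.
#' @return a [spectra_set()] with a `class` label column.
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed %||% config$seed)
  axis <- config_axis(config)
  n_neg <- config$n_per_class[1L]; n_pos <- config$n_per_class[2L]
  n <- n_neg + n_pos
  cls <- rep(config$class_labels, c(n_neg, n_pos))
  is_pos <- cls == config$class_labels[2L]
  amp <- outer(rep(1, n), config$peaks$amplitude)
  eff <- config$peaks$class_effect
  amp[is_pos, ] <- amp[is_pos, , drop = FALSE] *
    rep(eff, each = sum(is_pos))

  withr::with_seed(seed, {
    sim <- simulate_spectra(axis, config$peaks, amp,
                            config$scatter_slope_sd, config$scatter_offset_sd,
                            config$baseline_amplitude, config$noise_sd,
                            config$confounder_amplitude)
    n_out <- round(config$outlier_fraction * n)
    out_idx <- if (n_out > 0) sort(sample.int(n, n_out)) else integer(0)
  })
  x <- sim$x
  if (length(out_idx)) x[out_idx, ] <- x[out_idx, , drop = FALSE] * config$outlier_scale

  ids <- sprintf("s%03d", seq_len(n))
  labels <- tibble::tibble(sample_id = ids, class = cls)
  set <- spectra_set(x, axis, config$technique, labels = labels, sample_ids = ids)
  attr(set, "truth") <- tibble::tibble(
    sample_id = ids, class = cls, confounder = sim$u,
    is_outlier = seq_len(n) %in% out_idx
  )
  attr(set, "class_peaks") <- config$peaks$center[config$peaks$class_effect != 1]
  set
}

#' Write / read a synthetic config as YAML
#'
#' @param config a `synthetic_config`.
#' @param path file path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns the config.
#' @export
write_synthetic_config <- function(config, path) {
  obj <- unclass(config)
  obj$peaks <- as.data.frame(config$peaks)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  peaks <- dplyr::bind_rows(lapply(seq_along(obj$peaks$center), function(i) {
    tibble::tibble(center = obj$peaks$center[[i]], width = obj$peaks$width[[i]],
                   amplitude = obj$peaks$amplitude[[i]],
                   class_effect = obj$peaks$class_effect[[i]],
                   shape = obj$peaks$shape[[i]])
  }))
  args <- obj[setdiff(names(obj), "peaks")]
  do.call(synthetic_config, c(list(peaks = peaks), args))
}
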