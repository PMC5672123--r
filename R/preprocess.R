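#' Keep a spectral region
#'
#' Retains the variables whose axis position falls in the half-open interval
#' `[lo, hi)`; order is preserved. Selecting the standard 4000-7600 cm^-1 NIR
#' window from the 4000-10000 cm^-1 / 4 cm^-1 grid keeps 900 of 1500 points.
#'
#' @param set a `spectra_set`.
#' @param lo,hi interval ends on the increasing axis.
#' @return a `spectra_set` restricted to the region.
#' @export
select_region <- function(set, lo, hi) {
  keep <- in_interval(set$axis, lo, hi)
  if (!any(keep)) {
    abort_bad_arg(sprintf("region [%g, %g) selects no variables on axis [%g, %g]",
                          lo, hi, min(set$axis), max(set$axis)))
  }
  keep_attrs(set_replace(set, set$x[, keep, drop = FALSE], set$axis[keep]), set)
}

#' Drop spectral regions
#'
#' Removes every variable falling in any of the given `[lo, hi)` intervals
#' (union semantics; overlap is fine). Used e.g. to cut solvent and reference
#' signals (TMS at -0.2-0.2 ppm, methanol at 3.14-3.55 ppm) out of NMR spectra.
#'
#' @param set a `spectra_set`.
#' @param intervals list of length-2 numeric vectors `c(lo, hi)`.
#' @return a `spectra_set` on the complementary axis.
#' @export
remove_regions <- function(set, intervals) {
  if (!length(intervals)) return(set)
  drop <- Reduce(`|`, lapply(intervals, function(iv) {
    if (length(iv) != 2L || !(iv[1L] < iv[2L])) abort_bad_arg("each interval must be c(lo, hi) with lo < hi")
    in_interval(set$axis, iv[1L], iv[2L])
  }))
  if (all(drop)) abort_bad_arg("removal intervals cover the whole axis")
  keep_attrs(set_replace(set, set$x[, !drop, drop = FALSE], set$axis[!drop]), set)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Convolves each spectrum with the least-squares Savitzky-Golay kernel
#' (window `window`, polynomial order `polyorder`, derivative order `deriv`).
#' The first and last half-window points are fitted with asymmetric windows so
#' the output keeps the input length. Derivatives are scaled by the axis step,
#' so units are intensity per axis-unit^deriv. Requires a uniform axis.
#'
#' @param set a `spectra_set` on a uniform grid.
#' @param window odd window length `> polyorder`.
#' @param polyorder local polynomial degree.
#' @param deriv derivative order, `0 <= deriv <= polyorder`.
#' @return a filtered `spectra_set` on the same axis.
#' @export
savitzky_golay <- function(set, window = 11L, polyorder = 3L, deriv = 0L) {
  if (window %% 2L == 0L) {
    abort_bad_arg(sprintf("`window` must be odd; use %d or %d", window - 1L, window + 1L))
  }
  if (polyorder >= window) abort_bad_arg("`polyorder` must be < `window`")
  if (deriv < 0L || deriv > polyorder) abort_bad_arg("`deriv` must be in [0, polyorder]")
  if (window > n_variables(set)) abort_bad_arg("`window` exceeds the number of variables")
  steps <- diff(set$axis)
  h <- mean(steps)
  if ((max(steps) - min(steps)) > 1e-6 * abs(h)) {
    abort_bad_arg("Savitzky-Golay needs a uniformly spaced axis")
  }
  filt <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = h)
  x <- t(apply(set$x, 1L, signal::sgolayfilt, p = filt))
  keep_attrs(set_replace(set, x), set)
}

#' Multiplicative scatter correction
#'
#' Each spectrum `r` is regressed on a reference spectrum by ordinary least
#' squares, `r = m * ref + b`, and replaced by `(r - b) / m`, undoing
#' per-sample multiplicative and additive scatter. With `reference = "mean"`
#' the mean spectrum of `set` is used; pass the stored training reference when
#' correcting test data.
#'
#' @param set a `spectra_set`.
#' @param reference `"mean"` or a numeric vector of length `n_variables(set)`.
#' @return corrected `spectra_set`; the reference used is attached as
#'   `attr(, "msc_reference")`.
#' @export
msc <- function(set, reference = "mean") {
  ref <- if (identical(reference, "mean")) colMeans(set$x) else as.numeric(reference)
  if (length(ref) != n_variables(set)) abort_bad_arg("reference length must equal n_variables")
  ref_c <- ref - mean(ref)
  denom <- sum(ref_c^2)
  if (denom <= 0) abort_bad_arg("MSC reference has zero variance")
  slope <- as.vector(set$x %*% ref_c) / denom
  if (any(abs(slope) < 1e-12)) abort_bad_arg("MSC slope ~ 0 for at least one spectrum")
  intercept <- rowMeans(set$x) - slope * mean(ref)
  x <- (set$x - intercept) / slope
  out <- keep_attrs(set_replace(set, x), set)
  attr(out, "msc_reference") <- ref
  out
}

#' Normalise each spectrum to a fixed total integral
#'
#' Scales every row so that the sum of absolute intensities equals `total`
#' (default 100). Absolute values are used so the operation stays defined for
#' derivative spectra, which oscillate around zero.
#'
#' @param set a `spectra_set`.
#' @param total positive target integral.
#' @return normalised `spectra_set`.
#' @export
integral_normalize <- function(set, total = 100) {
  check_number(total, "total", lower = 0, strict = TRUE)
  sums <- rowSums(abs(set$x))
  if (any(sums <= 0)) {
    abort_bad_arg(sprintf("sample '%s' is all-zero and cannot be normalised",
                          rownames(set$x)[which(sums <= 0)[1L]]))
  }
  keep_attrs(set_replace(set, set$x * (total / sums)), set)
}

#' Uniform binning (bucketing)
#'
#' Splits the axis range into `n_bins` equal-width intervals (left-closed;
#' the last one closed on both sides so the axis maximum is kept) and sums the
#' member intensities of each bin, conserving total intensity exactly. The new
#' axis holds the bin centers. Empty bins get value 0 and are flagged in
#' `attr(, "empty_bins")`. Binning a dense 80501-point 0.5-9.5 ppm NMR
#' spectrum with `n_bins = 1100` yields the standard 1100-point fingerprint.
#'
#' @param set a `spectra_set`.
#' @param n_bins number of bins, `1 <= n_bins <= n_variables(set)`.
#' @return binned `spectra_set` with exactly `n_bins` variables.
#' @export
bin_uniform <- function(set, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) abort_bad_arg("`n_bins` must be >= 1")
  if (n_bins > n_variables(set)) abort_bad_arg("`n_bins` exceeds the number of variables")
  lo <- min(set$axis); hi <- max(set$axis)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(set$axis, breaks, rightmost.closed = TRUE)
  agg <- rowsum(t(set$x), group = idx) # bins present x samples
  x <- matrix(0, nrow(set$x), n_bins)
  x[, as.integer(rownames(agg))] <- t(agg)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  out <- keep_attrs(set_replace(set, x, centers), set)
  attr(out, "empty_bins") <- setdiff(seq_len(n_bins), as.integer(rownames(agg)))
  out
}

#' Fit / apply unit-variance autoscaling
#'
#' `fit_autoscaler()` learns per-variable means and standard deviations on a
#' training set; `apply_autoscaler()` centers and scales any set on the same
#' axis with those training statistics, so test data never leak into the
#' scaling. Variables with zero training variance are dropped with a warning
#' (they carry no information and would divide by zero); the scaler records
#' which.
#'
#' @param train a `spectra_set` with at least 2 samples.
#' @return `fit_autoscaler()`: an object of class `autoscaler` with fields
#'   `means`, `sds`, `keep` (retained variable mask) and the training axis.
#' @export
fit_autoscaler <- function(train) {
  if (n_samples(train) < 2L) abort_bad_arg("autoscaling needs >= 2 training samples")
  means <- colMeans(train$x)
  sds <- col_sds(train$x)
  scale_ref <- max(sds, 1e-300)
  keep <- sds > 1e-12 * scale_ref
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance variable(s) at axis position(s): %s",
                    sum(!keep),
                    paste(signif(train$axis[!keep], 6)[seq_len(min(5, sum(!keep)))],
                          collapse = ", ")), call. = FALSE)
  }
  structure(list(means = means, sds = sds, keep = keep, axis = train$axis),
            class = "autoscaler")
}

#' @rdname fit_autoscaler
#' @param scaler an `autoscaler`.
#' @param set a `spectra_set` on the training axis.
#' @export
apply_autoscaler <- function(scaler, set) {
  stopifnot(inherits(scaler, "autoscaler"))
  if (n_variables(set) != length(scaler$means)) {
    abort_bad_arg("variable count differs from the training set")
  }
  k <- scaler$keep
  x <- sweep(set$x[, k, drop = FALSE], 2L, scaler$means[k], `-`)
  x <- sweep(x, 2L, scaler$sds[k], `/`)
  keep_attrs(set_replace(set, x, set$axis[k]), set)
}
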