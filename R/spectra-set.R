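#' Construct a spectra set
#'
#' The central container of the package: a numeric matrix of intensities
#' (samples in rows, spectral variables in columns) sharing one spectral axis,
#' together with a technique tag and a per-sample label table. The axis is
#' normalised to strictly increasing order on construction; if it is supplied
#' decreasing (conventional for ppm), the columns are reversed consistently.
#'
#' @param x numeric matrix, `n_samples x n_vars`, no non-finite entries.
#' @param axis numeric vector of length `ncol(x)`, strictly monotone. Units are
#'   cm^-1 for IR techniques, ppm for NMR.
#' @param technique character scalar, conventionally one of `"ATR-mIR"`,
#'   `"NIR"`, `"NMR"`.
#' @param labels a data frame with a `sample_id` column covering every row of
#'   `x`, plus any label columns (e.g. `species`, `origin`).
#' @param sample_ids character vector of row identifiers; defaults to
#'   `rownames(x)` or `s1..sn`.
#'
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(x, axis, technique, labels = NULL, sample_ids = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) abort_bad_arg("`x` must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 2L) {
    abort_bad_arg("a spectra set needs at least 1 sample and 2 spectral variables")
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    abort_bad_arg(sprintf("non-finite intensity at sample row %d, variable column %d",
                          bad[1L], bad[2L]))
  }
  if (!is.numeric(axis) || length(axis) != ncol(x)) {
    abort_bad_arg(sprintf("`axis` has length %d but `x` has %d variables",
                          length(axis), ncol(x)))
  }
  d <- diff(axis)
  if (all(d < 0)) { # decreasing (ppm convention): normalise to increasing
    axis <- rev(axis)
    x <- x[, rev(seq_len(ncol(x))), drop = FALSE]
  } else if (!all(d > 0)) {
    abort_bad_arg("`axis` must be strictly monotone")
  }
  sample_ids <- sample_ids %||% rownames(x) %||% paste0("s", seq_len(nrow(x)))
  if (anyDuplicated(sample_ids)) abort_bad_arg("duplicated sample_ids")
  rownames(x) <- sample_ids
  colnames(x) <- NULL

  if (is.null(labels)) labels <- tibble::tibble(sample_id = sample_ids)
  labels <- tibble::as_tibble(labels)
  if (!"sample_id" %in% names(labels)) abort_bad_arg("`labels` needs a sample_id column")
  missing <- setdiff(sample_ids, labels$sample_id)
  if (length(missing)) {
    abort_bad_arg(sprintf("missing label row for sample_id '%s'", missing[1L]))
  }
  labels <- labels[match(sample_ids, labels$sample_id), , drop = FALSE]

  structure(
    list(x = x, axis = as.numeric(axis),
         technique = as.character(technique)[1L], labels = labels),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %s: %d samples x %d variables, axis [%g, %g]\n",
              x$technique, nrow(x$x), ncol(x$x), min(x$axis), max(x$axis)))
  lab <- setdiff(names(x$labels), "sample_id")
  if (length(lab)) cat("labels:", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / variables in a spectra set
#' @param set a `spectra_set`.
#' @return integer count.
#' @export
n_samples <- function(set) nrow(set$x)

#' @rdname n_samples
#' @export
n_variables <- function(set) ncol(set$x)

#' Subset a spectra set by sample
#'
#' @param set a `spectra_set`.
#' @param i integer or logical index, or character sample_ids.
#' @return a `spectra_set` with the selected samples, labels subset in step.
#' @export
subset_samples <- function(set, i) {
  if (is.character(i)) i <- match(i, rownames(set$x))
  x <- set$x[i, , drop = FALSE]
  out <- spectra_set(x, set$axis, set$technique,
                     labels = set$labels[match(rownames(x), set$labels$sample_id), ])
  keep_attrs(out, set)
}

# carry user attributes (planted truth etc.) across transformations
keep_attrs <- function(new, old) {
  tr <- attr(old, "truth")
  if (!is.null(tr)) {
    attr(new, "truth") <- tr[tr$sample_id %in% rownames(new$x), , drop = FALSE]
  }
  new
}

#' Coerce a spectra set to a long tibble
#'
#' One row per (sample, axis position); label columns are joined on.
#'
#' @param x a `spectra_set`.
#' @param ... unused.
#' @return a tibble with columns `sample_id`, `axis`, `intensity` and labels.
#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(rownames(x$x), times = ncol(x$x)),
    axis = rep(x$axis, each = nrow(x$x)),
    intensity = as.vector(x$x)
  )
  dplyr::left_join(long, x$labels, by = "sample_id")
}

#' Extract the intensity matrix
#' @param set a `spectra_set`.
#' @return the numeric matrix (samples x variables), rownames = sample ids.
#' @export
intensity_matrix <- function(set) set$x

# replace the matrix/axis keeping everything else; internal
set_replace <- function(set, x = set$x, axis = set$axis) {
  out <- set
  out$x <- x
  out$axis <- axis
  rownames(out$x) <- rownames(set$x)
  out
}

#' A single spectrum
#'
#' Lightweight one-sample record used by the JCAMP-DX reader/writer.
#'
#' @param axis,intensities equal-length numeric vectors; axis strictly monotone.
#' @param technique technique tag.
#' @param sample_id identifier.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(axis, intensities, technique = "NMR", sample_id = "s1") {
  if (length(axis) != length(intensities) || length(axis) < 2L) {
    abort_bad_arg("axis and intensities must have equal length >= 2")
  }
  if (!all(is.finite(intensities))) abort_bad_arg("non-finite intensities")
  d <- diff(axis)
  if (all(d < 0)) { axis <- rev(axis); intensities <- rev(intensities) }
  else if (!all(d > 0)) abort_bad_arg("axis must be strictly monotone")
  structure(list(axis = as.numeric(axis), intensities = as.numeric(intensities),
                 technique = technique, sample_id = sample_id),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s '%s': %d points, axis [%g, %g]\n", x$technique,
              x$sample_id, length(x$axis), min(x$axis), max(x$axis)))
  invisible(x)
}
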