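#' Read a delimited spectra matrix
#'
#' Expected layout: first row holds the spectral axis (first cell is a header
#' for the id column), each subsequent row is `sample_id` followed by that
#' sample's intensities. The delimiter (tab or comma) is auto-detected. Labels
#' live in a separate delimited file whose first column is `sample_id`;
#' remaining columns are label variables.
#'
#' A decreasing axis (ppm convention) is accepted and normalised to increasing
#' order with the intensity columns permuted consistently.
#'
#' @param path path to the matrix file.
#' @param labels_path path to the label table; `NULL` for no labels.
#' @param technique technique tag stored on the result.
#' @return a [spectra_set()].
#' @export
read_spectra_matrix <- function(path, labels_path = NULL, technique = "NMR") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort_format(sprintf("'%s': need a header row and at least one sample row", path))
  delim <- detect_delim(lines[[1L]])
  header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  axis <- parse_numeric_cells(header[-1L], row = 1L, offset = 1L, path = path)

  rows <- strsplit(lines[-1L], delim, fixed = TRUE)
  ids <- vapply(rows, `[[`, character(1L), 1L)
  n_vars <- length(axis)
  x <- matrix(NA_real_, length(rows), n_vars)
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1L]
    if (length(cells) != n_vars) {
      abort_format(sprintf("'%s': row %d has %d values but the axis has %d",
                           path, i + 1L, length(cells), n_vars))
    }
    x[i, ] <- parse_numeric_cells(cells, row = i + 1L, offset = 1L, path = path)
  }
  rownames(x) <- ids

  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- read_label_table(labels_path)
    missing <- setdiff(ids, labels$sample_id)
    if (length(missing)) {
      abort_format(sprintf("'%s': no label row for sample_id '%s'",
                           labels_path, missing[1L]))
    }
  }
  spectra_set(x, axis, technique, labels = labels, sample_ids = ids)
}

read_label_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  delim <- detect_delim(lines[[1L]])
  cells <- strsplit(lines, delim, fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] != "sample_id") {
    abort_format(sprintf("'%s': first label column must be 'sample_id'", path))
  }
  body <- cells[-1L]
  out <- lapply(seq_along(header), function(j) vapply(body, `[[`, character(1L), j))
  names(out) <- header
  tibble::as_tibble(out)
}

detect_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0L) "\t" else ","
}

parse_numeric_cells <- function(cells, row, offset, path) {
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !(cells %in% c("NA")))
  if (length(bad)) {
    abort_format(sprintf("'%s': non-numeric cell '%s' at row %d, column %d",
                         path, cells[bad[1L]], row, bad[1L] + offset))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    abort_format(sprintf("'%s': missing value at row %d, column %d", path, row, bad + offset))
  }
  vals
}

#' Write a spectra set as delimited text
#'
#' Inverse of [read_spectra_matrix()]: values are written with full double
#' precision so that write-then-read reproduces the set exactly.
#'
#' @param set a valid `spectra_set`.
#' @param path matrix file to create.
#' @param labels_path label file to create; `NULL` to skip.
#' @param delim `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_spectra_matrix <- function(set, path, labels_path = NULL, delim = "\t") {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$labels) != nrow(set$x)) abort_bad_arg("labels do not cover all samples")
  fmt <- function(v) sprintf("%.17g", v)
  header <- paste(c("sample_id", fmt(set$axis)), collapse = delim)
  body <- vapply(seq_len(nrow(set$x)), function(i) {
    paste(c(rownames(set$x)[i], fmt(set$x[i, ])), collapse = delim)
  }, character(1L))
  writeLines(c(header, body), path)
  if (!is.null(labels_path)) {
    lab <- set$labels
    lines <- c(paste(names(lab), collapse = delim),
               vapply(seq_len(nrow(lab)), function(i) {
                 paste(vapply(lab[i, ], as.character, character(1L)), collapse = delim)
               }, character(1L)))
    writeLines(lines, labels_path)
  }
  invisible(path)
}

#' Read a JCAMP-DX spectrum (AFFN only)
#'
#' Supports plain-numeric (AFFN) `##XYDATA=(X++(Y..Y))` blocks. The axis is
#' reconstructed linearly from `FIRSTX`/`LASTX`/`NPOINTS`; `XFACTOR`/`YFACTOR`
#' are applied. Compressed encodings (SQZ/DIF/DUP) are rejected.
#'
#' @param path file path.
#' @param technique technique tag for the result.
#' @return a [spectrum()].
#' @export
read_jcampdx <- function(path, technique = "NMR") {
  lines <- readLines(path)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", hit[[1L]]))
  }
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) abort_format(sprintf("'%s': no ##XYDATA block", path))
  firstx <- as.numeric(get_field("FIRSTX")); lastx <- as.numeric(get_field("LASTX"))
  npoints <- as.integer(get_field("NPOINTS"))
  if (anyNA(c(firstx, lastx, npoints))) {
    abort_format(sprintf("'%s': FIRSTX/LASTX/NPOINTS missing or non-numeric", path))
  }
  xfac <- as.numeric(get_field("XFACTOR") %||% "1")
  yfac <- as.numeric(get_field("YFACTOR") %||% "1")

  end <- grep("^##", lines)
  end <- end[end > start[[1L]]]
  data_lines <- lines[(start[[1L]] + 1L):(if (length(end)) end[[1L]] - 1L else length(lines))]
  data_lines <- trimws(data_lines[nzchar(trimws(data_lines))])
  if (any(grepl("[^0-9.+eE[:space:]-]", data_lines))) {
    abort_format(sprintf("'%s': non-AFFN (compressed?) data not supported", path))
  }
  ys <- lapply(strsplit(data_lines, "[[:space:]]+"), function(v) as.numeric(v)[-1L])
  y <- unlist(ys) * yfac
  if (length(y) != npoints) {
    abort_format(sprintf("'%s': %d data values but NPOINTS=%d", path, length(y), npoints))
  }
  axis <- (firstx + (lastx - firstx) * (seq_len(npoints) - 1L) / (npoints - 1L)) * xfac
  spectrum(axis, y, technique = technique,
           sample_id = get_field("TITLE") %||% basename(path))
}

#' Write a spectrum as JCAMP-DX (AFFN)
#'
#' @param spec a [spectrum()]; its axis must be (approximately) evenly spaced,
#'   as the format stores only `FIRSTX`/`LASTX`/`NPOINTS`.
#' @param path file to create.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  n <- length(spec$axis)
  step <- diff(spec$axis)
  if (max(step) - min(step) > 1e-6 * max(abs(spec$axis))) {
    abort_bad_arg("JCAMP-DX export needs an evenly spaced axis")
  }
  per_line <- 6L
  idx <- split(seq_len(n), ceiling(seq_len(n) / per_line))
  body <- vapply(idx, function(i) {
    paste(c(sprintf("%.10g", spec$axis[i[1L]]), sprintf("%.10g", spec$intensities[i])),
          collapse = " ")
  }, character(1L))
  writeLines(c(
    sprintf("##TITLE=%s", spec$sample_id),
    "##JCAMP-DX=4.24",
    sprintf("##DATA TYPE=%s SPECTRUM", spec$technique),
    "##XFACTOR=1", "##YFACTOR=1",
    sprintf("##FIRSTX=%.10g", spec$axis[1L]),
    sprintf("##LASTX=%.10g", spec$axis[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))",
    body,
    "##END="
  ), path)
  invisible(path)
}
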