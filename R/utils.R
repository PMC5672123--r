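# internal helpers shared across modules

abort_bad_arg <- function(msg) rlang::abort(msg, class = "authentispec_argument_error")
abort_format  <- function(msg) rlang::abort(msg, class = "authentispec_format_error")

# half-open interval membership on an increasing axis; the single interval
# convention used by every region operation in the package
in_interval <- function(axis, lo, hi) axis >= lo & axis < hi

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) abort_bad_arg(sprintf("`%s` must be > %g", name, lower))
  if (!strict && x < lower) abort_bad_arg(sprintf("`%s` must be >= %g", name, lower))
  invisible(x)
}

# column sd without the per-column apply() overhead
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt(colSums((x - rep(mu, each = n))^2) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
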