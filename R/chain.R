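#' Define a preprocessing chain
#'
#' A chain is an ordered list of step descriptors, each a list with a `step`
#' name plus parameters. Stateless steps (`select_region`, `remove_regions`,
#' `savitzky_golay`, `integral_normalize`, `bin_uniform`) act per spectrum;
#' stateful steps (`msc`, `osc`, `autoscale`) estimate their state on the
#' training partition inside [fit_chain()] and replay it on any other data,
#' so cross-validation never leaks test information.
#'
#' @param steps list of step descriptors, e.g.
#'   `list(list(step = "select_region", lo = 4000, hi = 7600),
#'         list(step = "autoscale"))`.
#' @return object of class `preprocess_chain`.
#' @export
preprocess_chain <- function(steps) {
  known <- c("select_region", "remove_regions", "savitzky_golay", "msc",
             "integral_normalize", "bin_uniform", "osc", "autoscale")
  for (s in steps) {
    if (is.null(s$step) || !s$step %in% known) {
      abort_bad_arg(sprintf("unknown chain step '%s'", s$step %||% "<missing>"))
    }
  }
  structure(list(steps = steps), class = "preprocess_chain")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  cat("<preprocess_chain>\n")
  for (s in x$steps) {
    pars <- s[setdiff(names(s), "step")]
    cat(sprintf("  %s(%s)\n", s$step,
                paste(sprintf("%s=%s", names(pars), vapply(pars, function(p)
                  paste(format(unlist(p)), collapse = ":"), character(1))),
                  collapse = ", ")))
  }
  invisible(x)
}

#' Default per-technique chains
#'
#' The conventional chains for the three techniques: correction steps first,
#' then normalisation, then scaling.
#' * `ATR-mIR`: select 800-1800 cm^-1, SG smoothing (11, 3), SG second
#'   derivative (11, 3), integral normalisation to 100, autoscale.
#' * `NIR`: select 4000-7600 cm^-1, SG second derivative, MSC against the
#'   training mean, a one-component OSC filter, autoscale.
#' * `NMR`: remove TMS (-0.2-0.2 ppm) and methanol (3.14-3.55 ppm), select
#'   0.5-9.5 ppm, bin to 1100 points, autoscale (no normalisation).
#'
#' @param technique `"ATR-mIR"`, `"NIR"` or `"NMR"`.
#' @return a [preprocess_chain()].
#' @export
default_chain <- function(technique) {
  switch(technique,
    "ATR-mIR" = preprocess_chain(list(
      list(step = "select_region", lo = 800, hi = 1800),
      list(step = "savitzky_golay", window = 11L, polyorder = 3L, deriv = 0L),
      list(step = "savitzky_golay", window = 11L, polyorder = 3L, deriv = 2L),
      list(step = "integral_normalize", total = 100),
      list(step = "autoscale")
    )),
    NIR = preprocess_chain(list(
      list(step = "select_region", lo = 4000, hi = 7600),
      list(step = "savitzky_golay", window = 11L, polyorder = 3L, deriv = 2L),
      list(step = "msc"),
      list(step = "osc", n_components = 1L),
      list(step = "autoscale")
    )),
    NMR = preprocess_chain(list(
      list(step = "remove_regions", intervals = list(c(-0.2, 0.2), c(3.14, 3.55))),
      list(step = "select_region", lo = 0.5, hi = 9.5),
      list(step = "bin_uniform", n_bins = 1100L),
      list(step = "autoscale")
    )),
    abort_bad_arg(sprintf("no default chain for technique '%s'", technique))
  )
}

#' Fit a chain on training data and apply it elsewhere
#'
#' `fit_chain()` walks the chain over the training set, estimating the state
#' of every stateful step (MSC reference, OSC filter, autoscaler) on the
#' training data only, and returns both the fitted chain and the transformed
#' training set. `apply_chain()` replays a fitted chain on new data using the
#' stored training state. The `osc` step needs the coded class response `y`
#' of the training samples.
#'
#' @param chain a `preprocess_chain`.
#' @param train a `spectra_set`.
#' @param y numeric coded response (+1/-1) for the training samples; required
#'   if the chain contains an `osc` step.
#' @return `fit_chain()`: list with `fitted` (class `fitted_chain`) and
#'   `train` (the transformed training `spectra_set`).
#' @export
fit_chain <- function(chain, train, y = NULL) {
  stopifnot(inherits(chain, "preprocess_chain"))
  set <- train
  fitted_steps <- vector("list", length(chain$steps))
  for (i in seq_along(chain$steps)) {
    s <- chain$steps[[i]]
    state <- NULL
    set <- switch(s$step,
      select_region = select_region(set, s$lo, s$hi),
      remove_regions = remove_regions(set, s$intervals),
      savitzky_golay = savitzky_golay(set, s$window %||% 11L,
                                      s$polyorder %||% 3L, s$deriv %||% 0L),
      integral_normalize = integral_normalize(set, s$total %||% 100),
      bin_uniform = bin_uniform(set, s$n_bins),
      msc = {
        out <- msc(set, reference = s$reference %||% "mean")
        state <- list(reference = attr(out, "msc_reference"))
        out
      },
      osc = {
        if (is.null(y)) abort_bad_arg("chain has an `osc` step but no `y` was given")
        mu <- colMeans(set$x)
        filt <- fit_osc(sweep(set$x, 2L, mu, `-`), y,
                        n_components = s$n_components %||% 1L,
                        tol = s$tol %||% 1e-8)
        corrected <- apply_osc(filt, sweep(set$x, 2L, mu, `-`))
        state <- list(filter = filt, means = mu)
        keep_attrs(set_replace(set, sweep(corrected, 2L, mu, `+`)), set)
      },
      autoscale = {
        sc <- fit_autoscaler(set)
        state <- list(scaler = sc)
        apply_autoscaler(sc, set)
      }
    )
    fitted_steps[[i]] <- c(s, list(.state = state))
  }
  list(fitted = structure(list(steps = fitted_steps), class = "fitted_chain"),
       train = set)
}

#' @rdname fit_chain
#' @param fitted a `fitted_chain` from [fit_chain()].
#' @param set a `spectra_set` on the training axis.
#' @export
apply_chain <- function(fitted, set) {
  stopifnot(inherits(fitted, "fitted_chain"))
  for (s in fitted$steps) {
    set <- switch(s$step,
      select_region = select_region(set, s$lo, s$hi),
      remove_regions = remove_regions(set, s$intervals),
      savitzky_golay = savitzky_golay(set, s$window %||% 11L,
                                      s$polyorder %||% 3L, s$deriv %||% 0L),
      integral_normalize = integral_normalize(set, s$total %||% 100),
      bin_uniform = bin_uniform(set, s$n_bins),
      msc = msc(set, reference = s$.state$reference),
      osc = {
        centered <- sweep(set$x, 2L, s$.state$means, `-`)
        corrected <- apply_osc(s$.state$filter, centered)
        keep_attrs(set_replace(set, sweep(corrected, 2L, s$.state$means, `+`)), set)
      },
      autoscale = apply_autoscaler(s$.state$scaler, set)
    )
  }
  set
}

# chain restricted to per-sample steps, as used for PCA-based QC: quality
# checking precedes classifier construction, and also precedes every step
# whose state (MSC reference, OSC filter, scaler) is estimated from the
# cohort — outliers must not contaminate that state before they are caught
qc_chain <- function(chain) {
  preprocess_chain(Filter(function(s) !s$step %in% c("msc", "osc", "autoscale"),
                          chain$steps))
}
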