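#' Fit an orthogonal signal correction (OSC) filter
#'
#' Estimates, on training data only, spectral components whose scores are
#' orthogonal to the class response, and removes them. Each component solves
#' the defining optimisation directly: find the score `t` maximising the
#' explained X-variance subject to `t` lying in the column space of `X` and
#' `t'y = 0`. Writing `U` for an orthonormal basis of the (numerical) column
#' space and `B` for an orthonormal basis of the part of `U` orthogonal to
#' `y`, the solution is the top eigenvector of `B'XX'B`; the weight vector
#' `w` is chosen (via the pseudo-inverse on the retained singular
#' subspace) so that `X w = t` exactly on the training data, which makes the
#' filter reproducible and idempotent. The loading is `p = X't / t't` and
#' `t p'` is deflated from `X`; further components repeat on the deflated
#' matrix. This closed-form solution is the fixed point the classical
#' iterative scheme (orthogonalise the score against `y`, re-estimate,
#' re-project) aims for, computed without an iteration that can stall.
#'
#' If the matrix holds no structure orthogonal to `y` (e.g. rank-1 spectra
#' whose scores are proportional to `y`), the component is returned as null
#' (zero weight/loading) and removes nothing.
#'
#' @param x centered numeric matrix (samples x variables). Centering is the
#'   caller's responsibility; inside a chain the training means are used.
#' @param y numeric coded response (+1/-1), both classes present.
#' @param n_components number of orthogonal components to remove (default 1:
#'   the filter is conventionally applied once).
#' @param tol relative singular-value cutoff defining the numerical column
#'   space of `x`.
#' @return object of class `osc_filter`: `weights` and `loadings`
#'   (variables x components, with `X_train w = t`), training `scores`,
#'   `removed_variance` and `total_variance` (squared Frobenius norms), and
#'   `n_vars`.
#' @export
fit_osc <- function(x, y, n_components = 1L, tol = 1e-8) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 3L) abort_bad_arg("OSC needs at least 3 training samples")
  y <- as.numeric(y)
  if (length(y) != nrow(x)) abort_bad_arg("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2L) abort_bad_arg("`y` must contain both classes")

  p <- ncol(x)
  n <- nrow(x)
  total_var <- sum(x^2)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  xd <- x
  y_unit <- y / sqrt(sum(y^2))

  null_component <- function() {
    W <<- cbind(W, 0); P <<- cbind(P, 0); Tm <<- cbind(Tm, 0)
  }

  for (comp in seq_len(n_components)) {
    if (sum(xd^2) <= 1e-30 * max(total_var, 1)) { null_component(); next }
    sv <- svd(xd)
    keep <- sv$d > tol * sv$d[1L]
    U <- sv$u[, keep, drop = FALSE]
    r <- ncol(U)
    # orthonormal basis B of {u in span(U) : u'y = 0}
    uy <- crossprod(U, y_unit) # r x 1
    if (sqrt(sum(uy^2)) < 1e-12) {
      B <- U # whole column space already orthogonal to y
    } else if (r == 1L) {
      null_component(); next # only structure is along y
    } else {
      Q <- qr.Q(qr(uy), complete = TRUE)[, -1L, drop = FALSE] # r x (r-1)
      B <- U %*% Q
    }
    # maximise ||X't||^2 over unit t in span(B): top eigenvector of B'XX'B
    M <- crossprod(crossprod(xd, B)) # (X'B)'(X'B) = B'XX'B
    eg <- eigen(M, symmetric = TRUE)
    if (eg$values[1L] <= 1e-30 * max(total_var, 1)) { null_component(); next }
    t_score <- as.vector(B %*% eg$vectors[, 1L]) # unit norm
    # weight reproducing t on the training data: w = V D^-1 U' t
    w <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(U, t_score) / sv$d[keep])
    t_score <- as.vector(xd %*% w) # identical to t_score up to rounding
    p_load <- crossprod(xd, t_score) / sum(t_score^2)
    xd <- xd - tcrossprod(t_score, p_load)
    W <- cbind(W, as.vector(w)); P <- cbind(P, as.vector(p_load))
    Tm <- cbind(Tm, t_score)
  }

  structure(list(
    weights = W, loadings = P, scores = Tm, n_components = ncol(W),
    n_vars = p, removed_variance = total_var - sum(xd^2),
    total_variance = total_var
  ), class = "osc_filter")
}

#' Apply an OSC filter to new spectra
#'
#' Sequentially computes each component's score on the new (centered) data
#' from the stored weights and subtracts its loading contribution:
#' `X <- X - (X w) p'`. Applying the filter to the training matrix reproduces
#' the fit-time deflation, and a second application is a no-op.
#'
#' @param filter an `osc_filter`.
#' @param x centered matrix on the training variables.
#' @return the corrected matrix.
#' @export
apply_osc <- function(filter, x) {
  stopifnot(inherits(filter, "osc_filter"))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) != filter$n_vars) {
    abort_bad_arg(sprintf("x has %d variables but the filter was trained on %d",
                          ncol(x), filter$n_vars))
  }
  for (a in seq_len(filter$n_components)) {
    t_new <- x %*% filter$weights[, a, drop = FALSE]
    x <- x - tcrossprod(as.vector(t_new), filter$loadings[, a])
  }
  x
}

#' @export
print.osc_filter <- function(x, ...) {
  cat(sprintf("<osc_filter> %d component(s) over %d variables; removed %.1f%% of variance\n",
              x$n_components, x$n_vars,
              100 * x$removed_variance / max(x$total_variance, 1e-300)))
  invisible(x)
}
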