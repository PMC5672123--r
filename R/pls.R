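# coded class response: positive -> +1, negative -> -1, threshold 0
code_classes <- function(labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) {
    abort_bad_arg(sprintf("need exactly two classes, got: %s", paste(lev, collapse = ", ")))
  }
  positive <- positive %||% lev[2L]
  if (!positive %in% lev) abort_bad_arg(sprintf("positive class '%s' not present", positive))
  negative <- setdiff(lev, positive)
  list(y = ifelse(labels == positive, 1, -1), positive = positive, negative = negative)
}

resolve_xy <- function(x, labels, positive) {
  if (inherits(x, "spectra_set")) {
    if (is.character(labels) && length(labels) == 1L) labels <- x$labels[[labels]]
    axis <- x$axis
    x <- x$x
  } else {
    axis <- NULL
    x <- as.matrix(x)
  }
  cc <- code_classes(labels, positive)
  list(x = x, axis = axis, coding = cc)
}

#' Fit a PLS-DA classifier (NIPALS PLS1)
#'
#' Partial least squares regression on the coded class response
#' (+1 = positive class, -1 = negative), fitted by NIPALS with sequential
#' deflation. For a single response each component has the closed NIPALS
#' form: `w = X'y` normalised, `t = Xw`, `p = X't/t't`, `q = y't/t't`,
#' then `X <- X - tp'`, `y <- y - qt`. Prediction uses the regression vector
#' `b = W (P'W)^{-1} q`.
#'
#' @param x numeric matrix (samples x variables), already preprocessed/scaled
#'   by the chain, or a `spectra_set`.
#' @param labels two-class label vector, or (for a `spectra_set`) the name of
#'   a label column.
#' @param ncomp number of predictive components `A`.
#' @param positive label coded +1; defaults to the alphabetically second.
#' @return object of class `pls_model`.
#' @export
fit_plsda <- function(x, labels, ncomp = 2L, positive = NULL) {
  rx <- resolve_xy(x, labels, positive)
  x <- rx$x
  y <- rx$coding$y
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) abort_bad_arg("`ncomp` must be >= 1")

  x_means <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2L, x_means, `-`)
  yc <- y - y_mean
  p <- ncol(x)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, nrow(x), ncomp)
  q <- numeric(ncomp)
  x_scale <- sum(xc^2)
  for (a in seq_len(ncomp)) {
    w <- crossprod(xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(max(x_scale, 1))) {
      abort_bad_arg(sprintf("`ncomp` = %d exceeds the informative rank; max usable is %d",
                            ncomp, a - 1L))
    }
    w <- w / nw
    t_a <- as.vector(xc %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-24 * max(x_scale, 1)) {
      abort_bad_arg(sprintf("`ncomp` = %d exceeds the rank; max usable is %d", ncomp, a - 1L))
    }
    P[, a] <- crossprod(xc, t_a) / tt
    q[a] <- sum(yc * t_a) / tt
    W[, a] <- w
    Tm[, a] <- t_a
    xc <- xc - tcrossprod(t_a, P[, a])
    yc <- yc - q[a] * t_a
  }
  b <- W %*% solve(crossprod(P, W), q)
  structure(list(
    ncomp = ncomp, weights = W, x_loadings = P, y_loadings = q,
    scores = Tm, coefficients = as.vector(b),
    x_means = x_means, y_mean = y_mean, axis = rx$axis,
    positive = rx$coding$positive, negative = rx$coding$negative
  ), class = "pls_model")
}

#' Fit an oPLS-DA classifier
#'
#' Orthogonal-projection PLS-DA: `n_orth` components whose loadings are
#' orthogonalised against the predictive direction are extracted and deflated
#' from `X`, then a single predictive PLS component is fitted on the cleaned
#' matrix. Per orthogonal component: with `w = X'y` (normalised),
#' `t = Xw`, `p = X't/t't`, the orthogonal weight is
#' `w_o = p - (w'p) w` (normalised), `t_o = X w_o`, `p_o = X't_o / t_o't_o`,
#' and `X <- X - t_o p_o'`. Orthogonal scores are orthogonal to the response
#' by construction. With `n_orth = 0` the model coincides with
#' `fit_plsda(ncomp = 1)`.
#'
#' @inheritParams fit_plsda
#' @param n_orth number of orthogonal components (>= 0).
#' @return object of class `opls_model`.
#' @export
fit_oplsda <- function(x, labels, n_orth = 1L, positive = NULL) {
  rx <- resolve_xy(x, labels, positive)
  x <- rx$x
  y <- rx$coding$y
  n_orth <- as.integer(n_orth)
  if (n_orth < 0L) abort_bad_arg("`n_orth` must be >= 0")

  x_means <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2L, x_means, `-`)
  yc <- y - y_mean
  p <- ncol(x)
  x_scale <- max(sum(xc^2), 1e-300)

  w <- crossprod(xc, yc)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12 * sqrt(x_scale)) abort_bad_arg("no class-correlated structure in X")
  w <- w / nw

  # first loading on the undeflated matrix: the loading of the y-correlated
  # direction in the raw data. Orthogonal deflation leaves w (and hence this
  # direction) unchanged, so it is the stable quantity to compare across
  # resamplings, for both model families.
  t0 <- as.vector(xc %*% w)
  p_first <- as.vector(crossprod(xc, t0) / sum(t0^2))

  W_o <- P_o <- matrix(0, p, n_orth)
  T_o <- matrix(0, nrow(x), n_orth)
  for (j in seq_len(n_orth)) {
    t_p <- as.vector(xc %*% w)
    p_p <- crossprod(xc, t_p) / sum(t_p^2)
    w_o <- p_p - as.numeric(crossprod(w, p_p)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-12) {
      abort_bad_arg(sprintf("no orthogonal structure left for component %d", j))
    }
    w_o <- w_o / nwo
    t_o <- as.vector(xc %*% w_o)
    p_o <- crossprod(xc, t_o) / sum(t_o^2)
    xc <- xc - tcrossprod(t_o, p_o)
    W_o[, j] <- w_o; P_o[, j] <- p_o; T_o[, j] <- t_o
  }
  # single predictive component on the deflated matrix
  t_pred <- as.vector(xc %*% w)
  tt <- sum(t_pred^2)
  p_pred <- crossprod(xc, t_pred) / tt
  q_pred <- sum(yc * t_pred) / tt
  structure(list(
    n_orth = n_orth, w = as.vector(w), p = as.vector(p_pred),
    p_first = p_first, q = q_pred,
    W_orth = W_o, P_orth = P_o, scores = t_pred, orth_scores = T_o,
    x_means = x_means, y_mean = y_mean, axis = rx$axis,
    positive = rx$coding$positive, negative = rx$coding$negative
  ), class = "opls_model")
}

#' Predict continuous decision scores
#'
#' Returns predictions in coded units (+1 = positive class); values above 0
#' classify positive. `newdata` must already be preprocessed with the
#' training chain (same scaler/MSC reference/OSC filter).
#'
#' @param object a fitted `pls_model` or `opls_model`.
#' @param newdata matrix or `spectra_set` on the training variables.
#' @param ... unused.
#' @return numeric score vector.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "spectra_set")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(object$x_means)) {
    abort_bad_arg(sprintf("newdata has %d variables; model was trained on %d",
                          ncol(x), length(object$x_means)))
  }
  as.vector(object$y_mean + sweep(x, 2L, object$x_means, `-`) %*% object$coefficients)
}

#' @rdname predict.pls_model
#' @export
predict.opls_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "spectra_set")) newdata$x else as.matrix(newdata)
  if (ncol(x) != length(object$x_means)) {
    abort_bad_arg(sprintf("newdata has %d variables; model was trained on %d",
                          ncol(x), length(object$x_means)))
  }
  xc <- sweep(x, 2L, object$x_means, `-`)
  for (j in seq_len(object$n_orth)) {
    t_o <- xc %*% object$W_orth[, j, drop = FALSE]
    xc <- xc - tcrossprod(as.vector(t_o), object$P_orth[, j])
  }
  as.vector(object$y_mean + (xc %*% object$w) * object$q)
}

#' Classify samples with a fitted model
#'
#' Applies the fixed threshold 0 to the continuous scores; exact ties go to
#' the negative class.
#'
#' @param model a `pls_model` or `opls_model`.
#' @param newdata matrix or `spectra_set` on the training variables.
#' @return character vector of predicted labels.
#' @export
classify <- function(model, newdata) {
  scores <- stats::predict(model, newdata)
  ifelse(scores > 0, model$positive, model$negative)
}

# first x-loading, named by axis position where available; for oPLS the
# loading of the predictive direction on the undeflated training matrix
first_loading <- function(model) {
  v <- if (inherits(model, "opls_model")) model$p_first else model$x_loadings[, 1L]
  nm <- model$axis
  if (!is.null(nm)) names(v) <- format(nm, trim = TRUE) else names(v) <- seq_along(v)
  v
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d variables; '%s' (+1) vs '%s' (-1)\n",
              x$ncomp, length(x$x_means), x$positive, x$negative))
  invisible(x)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal component(s), %d variables; '%s' (+1) vs '%s' (-1)\n",
              x$n_orth, length(x$x_means), x$positive, x$negative))
  invisible(x)
}

#' Tidy a fitted classifier
#'
#' One row per variable and component, with weights and loadings.
#'
#' @param x a `pls_model` or `opls_model`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  axis <- x$axis %||% seq_along(x$x_means)
  purrr::map_dfr(seq_len(x$ncomp), function(a) {
    tibble::tibble(component = a, axis = axis,
                   weight = x$weights[, a], loading = x$x_loadings[, a])
  })
}

#' @rdname tidy.pls_model
#' @method tidy opls_model
#' @export
tidy.opls_model <- function(x, ...) {
  axis <- x$axis %||% seq_along(x$x_means)
  dplyr::bind_rows(
    tibble::tibble(component = "predictive", axis = axis,
                   weight = x$w, loading = x$p),
    purrr::map_dfr(seq_len(x$n_orth), function(j) {
      tibble::tibble(component = paste0("orthogonal", j), axis = axis,
                     weight = x$W_orth[, j], loading = x$P_orth[, j])
    })
  )
}

#' @rdname tidy.pls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n_vars = length(x$x_means),
                 positive = x$positive, negative = x$negative)
}

#' @rdname tidy.pls_model
#' @method glance opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(n_orth = x$n_orth, n_vars = length(x$x_means),
                 positive = x$positive, negative = x$negative)
}
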