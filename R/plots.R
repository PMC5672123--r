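# ggplot2 front-ends for the main result types

#' Plot spectra
#'
#' Overlays (a subset of) the spectra, coloured by a label column.
#'
#' @param set a `spectra_set`.
#' @param colour_by label column name, or `NULL`.
#' @param n_max at most this many samples are drawn.
#' @return a ggplot object.
#' @export
plot_spectra <- function(set, colour_by = NULL, n_max = 20L) {
  ids <- rownames(set$x)
  if (length(ids) > n_max) ids <- ids[seq_len(n_max)]
  df <- as_tibble(subset_samples(set, ids))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis, y = .data$intensity,
                                        group = .data$sample_id))
  p <- if (is.null(colour_by)) p + ggplot2::geom_line(alpha = 0.6) else
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour_by]]), alpha = 0.6)
  p + ggplot2::labs(x = if (set$technique == "NMR") "ppm" else
    expression(wavenumber ~ (cm^-1)), y = "intensity",
    title = sprintf("%s spectra", set$technique))
}

#' @method autoplot component_curve
#' @export
autoplot.component_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ncomp, y = .data$q2_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q2_mean - .data$q2_sd,
                                          ymax = .data$q2_mean + .data$q2_sd)) +
    ggplot2::geom_point(data = object[object$optimum, ], colour = "red", size = 3) +
    ggplot2::labs(x = "model complexity (components)",
                  y = expression(Q^2),
                  title = sprintf("%s: cross-validated Q2 vs complexity",
                                  attr(object, "family")))
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("pooled ROC, AUC = %.3f", object$auc))
}

#' @method autoplot stability_result
#' @export
autoplot.stability_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::transmute(object, position = .data$position,
                     `|mean loading|` = abs(.data$mean),
                     `relative error` = .data$rel_error),
    -"position", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "variables, sorted by decreasing |mean loading|",
                  y = NULL, title = "first-loading stability across splits")
}

#' @method autoplot auc_distribution
#' @export
autoplot.auc_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-split AUC")
}
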