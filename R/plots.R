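#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Accuracy-vs-exclusion curves
#'
#' Mean cross-run accuracy (plus/minus one standard error across subjects)
#' against the number of ignored transition frames, one curve per modality.
#'
#' @param object An `accuracy_table` (the `accuracy` element of a
#'   [run_experiment()] result) or the pre-aggregated curve tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_table <- function(object, ...) {
  curve <- accuracy_curve(object)
  gg <- ggplot2::ggplot(curve, ggplot2::aes(
    x = .data$k_ignore, y = .data$mean_accuracy,
    colour = .data$modality, group = .data$modality))
  if (any(is.finite(curve$se))) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$se,
                   ymax = .data$mean_accuracy + .data$se),
      width = 0.1, na.rm = TRUE)
  }
  gg + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ignored transition frames (per side)",
                  y = "mean cross-run accuracy", colour = NULL) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' @export
autoplot.bs_experiment <- function(object, ...) {
  autoplot.accuracy_table(object$accuracy, ...)
}

#' Slice maps of a permutation result
#'
#' Axial-slice raster of the normalized weight map with significant voxels
#' (empirical `p < alpha`) outlined by tile colour.
#'
#' @param object A `perm_result`.
#' @param slices Integer z-slices to show (default: all present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_result <- function(object, slices = NULL, ...) {
  df <- tidy.perm_result(object)
  if (!is.null(slices)) df <- df[df$z %in% slices, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$weight)) +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 0, size = 1, colour = "red") +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "normalized\nweight") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
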