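#' Plot a chromatogram trace
#'
#' @param trace A chromatogram tibble at any stage.
#' @return A ggplot object (intensity vs retention time).
#' @export
plot_chromatogram <- function(trace) {
  stage <- trace_stage(trace)
  ylab <- switch(stage,
                 raw = "intensity (a.u.)",
                 logged = "log10 intensity",
                 baseline_corrected = "corrected log10 intensity")
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$rt_min,
                                      y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "retention time (min)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot per-class input sensitivities
#'
#' @param sens A sensitivity tibble from [sensitivity_analysis()].
#' @return A ggplot bar chart, one facet per class.
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$peak,
                                     y = .data$sensitivity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~class, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "sensitivity (output range)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the feature-search trace
#'
#' Mean cross-validated CCR against the cumulative number of inputs at
#' each step of the sequential rank-based addition; the selected step is
#' highlighted.
#'
#' @param object An evaluated selection trace (see [evaluate_trace()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eo_selection_trace <- function(object, ...) {
  if (!"ccr_internal" %in% names(object))
    stop("trace has no CCR column; run evaluate_trace() first",
         call. = FALSE)
  best <- attr(object, "best_step")
  df <- tidyr::pivot_longer(
    object[c("n_cumulative", "ccr_internal", "ccr_external")],
    cols = dplyr::starts_with("ccr"),
    names_to = "set", values_to = "ccr")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_cumulative,
                                        y = .data$ccr,
                                        colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of input peaks", y = "mean CCR",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(best))
    p <- p + ggplot2::geom_vline(xintercept = object$n_cumulative[best],
                                 linetype = "dashed")
  p
}

#' Plot an averaged confusion matrix
#'
#' @param object An `eo_cv` object.
#' @param ... Unused.
#' @return A ggplot heat map of the row-normalized percentage confusion
#'   matrix.
#' @export
autoplot.eo_cv <- function(object, ...) {
  m <- object$confusion
  df <- tidyr::expand_grid(true = seq_len(nrow(m)),
                           predicted = seq_len(ncol(m)))
  df$percent <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$percent)), colour = "white") +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(m))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m))) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' Plot the permutation-test CCR distributions
#'
#' Histograms (density-normalized, so each integrates to 1) of the
#' external CCR under the real and the permuted labels.
#'
#' @param object An `eo_permtest` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eo_permtest <- function(object, bins = 20, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ccr_external,
                                   fill = .data$labels)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "external CCR", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
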