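#' Plot a ROC curve
#'
#' @param object An `ici_roc` object from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ici_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = object$fpr, tpr = object$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (%s)", auc(object), object$orientation)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-marker AUC ranges across cohorts
#'
#' Point-range plot of each marker's minimum, mean and maximum AUC over
#' the cohorts it was evaluable on.
#'
#' @param summary Tibble from [summarize_markers()].
#' @return A ggplot.
#' @export
plot_marker_summary <- function(summary) {
  df <- dplyr::mutate(summary,
                      marker = stats::reorder(.data$marker, .data$auc_mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc_mean, y = .data$marker)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$auc_min,
                                          xmax = .data$auc_max)) +
    ggplot2::labs(x = "AUC (min / mean / max across cohorts)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the holdout AUC distribution
#'
#' @param object An `ici_cv` object from [repeated_holdout()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ici_cv <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean_auc, colour = "red") +
    ggplot2::labs(
      x = "Test-set AUC", y = "Iterations",
      title = sprintf("Repeated holdout: mean AUC %.3f over %d iterations",
                      object$mean_auc, object$valid_iterations)
    ) +
    ggplot2::theme_minimal()
}

#' Plot marker frequencies among acceptable combinations
#'
#' @param object An `ici_freq_report` object from [frequency_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ici_freq_report <- function(object, ...) {
  df <- dplyr::mutate(object$frequency,
                      marker = stats::reorder(.data$marker, .data$frequency))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$marker)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(
      x = sprintf("Frequency among combinations with AUC >= %.2f",
                  object$auc_floor),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
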