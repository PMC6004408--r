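# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an applicability-domain curve
#'
#' True positive rate per similarity bin against distance to the training set
#' (1 - mean k-NN similarity), point size proportional to bin support.
#'
#' @param object A `moa_ad_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moa_ad_curve <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$distance, y = .data$tpr)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "distance to training set (1 - mean k-NN Tanimoto)",
      y = "true positive rate",
      title = sprintf("Applicability domain (k = %d), AD-AUC = %.3f",
                      object$k, object$ad_auc),
      size = "compounds"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-target metric distributions
#'
#' Boxplots of precision, recall and F1 per label over targets.
#'
#' @param object A `moa_metrics` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moa_metrics <- function(object, ...) {
  long <- object$per_target |>
    filter(.data$valid) |>
    pivot_longer(all_of(c("precision", "recall", "f1")),
                 names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "per-target value") +
    ggplot2::theme_minimal()
}

#' Plot nearest-neighbor similarity distributions
#'
#' Distribution of per-compound nearest-neighbor Tanimoto similarity for the
#' activator-inhibitor (A-I), binder-activator (B-A) and binder-inhibitor
#' (B-I) pairings, with the overall medians annotated.
#'
#' @param nn Output of [nn_similarity_analysis()].
#' @return A ggplot.
#' @export
plot_nn_similarity <- function(nn) {
  med <- nn_similarity_medians(nn)
  ggplot2::ggplot(nn, ggplot2::aes(x = .data$pairing, y = .data$nn_tc,
                                   fill = .data$pairing)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::geom_point(data = med, ggplot2::aes(y = .data$median_tc),
                        shape = 23, size = 2.5, fill = "white") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "nearest-neighbor Tanimoto similarity") +
    ggplot2::theme_minimal()
}
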