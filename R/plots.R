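#' Plot an ROC curve
#'
#' @param object A [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the per-feature ROC curves of a cohort evaluation
#'
#' @param object A `cohort_evaluation`.
#' @param ... Unused.
#' @return A ggplot object faceted by feature.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_evaluation <- function(object, ...) {
  pts <- purrr::map_dfr(object$per_feature, function(f) {
    dplyr::mutate(f$roc$points,
                  feature = sprintf("%s (AUC %.3f)", f$feature, f$auc))
  })
  pts <- dplyr::arrange(pts, .data$feature, .data$fpr, .data$sensitivity)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::facet_wrap(~feature) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

#' Boxplots of the three features by group
#'
#' Mirrors the usual group-comparison figure: boxplots of SD, mean and
#' entropy for the normal and abnormal groups, with the QV cut-offs as
#' reference lines.
#'
#' @param features Feature tibble with `group`, `sd`, `mean`, `entropy`.
#' @param qv Optional [qv_thresholds()] drawn as dashed reference lines.
#' @return A ggplot object.
#' @export
plot_feature_groups <- function(features, qv = qv_thresholds()) {
  long <- tidyr::pivot_longer(
    features[, c("group", "sd", "mean", "entropy")],
    cols = c("sd", "mean", "entropy"),
    names_to = "feature", values_to = "value"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Feature value") +
    ggplot2::theme_minimal()
  if (!is.null(qv)) {
    ref <- tibble(feature = names(qv), value = as.numeric(qv))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed", colour = "red3")
  }
  p
}
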