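#' Plot an empirical ROC curve
#'
#' Step curve in 1 - specificity vs sensitivity space with the chance
#' diagonal and the Youden-optimal operating point marked.
#'
#' @param object an `abpm_roc` from [roc_analysis()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.abpm_roc <- function(object, ...) {
  cv <- object$curve[order(1 - object$curve$specificity, object$curve$sensitivity), ]
  df <- tibble::tibble(fpr = c(0, 1 - cv$specificity, 1),
                       tpr = c(0, cv$sensitivity, 1))
  opt <- tibble::tibble(fpr = 1 - object$youden_specificity,
                        tpr = object$youden_sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_point(data = opt, colour = "#b2182b", size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: AUC %.2f (%.0f%% CI %.2f-%.2f)", object$auc,
                      100 * object$conf_level, object$auc_ci[1],
                      object$auc_ci[2]),
      subtitle = sprintf("Youden cut-point %.4g", object$youden_cutoff)) +
    ggplot2::theme_minimal()
}

#' Bar chart of diagnostic accuracy by parameter
#'
#' Accuracy of the full discriminant model next to each single ABPM
#' parameter, sorted by accuracy.
#'
#' @param ranking tibble with `parameter` and `accuracy` (proportion), as
#'   produced by [run_fit_eval()].
#' @return a ggplot object.
#' @export
plot_accuracy_ranking <- function(ranking) {
  stopifnot(all(c("parameter", "accuracy") %in% names(ranking)))
  df <- dplyr::mutate(ranking,
                      parameter = stats::reorder(.data$parameter, .data$accuracy),
                      is_lda = grepl("LDA", .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter,
                                   y = 100 * .data$accuracy,
                                   fill = .data$is_lda)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#92c5de", `TRUE` = "#2166ac")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Accuracy (%)",
                  title = "Autonomic-failure prediction accuracy by parameter") +
    ggplot2::theme_minimal()
}
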