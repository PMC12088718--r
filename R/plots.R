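# ggplot2 displays for evaluation results.

roc_points <- function(labels, probs) {
  ord <- order(probs, decreasing = TRUE)
  labels <- labels[ord]
  tibble(fpr = c(0, cumsum(labels == 0) / sum(labels == 0)),
         tpr = c(0, cumsum(labels == 1) / sum(labels == 1)))
}

#' Plot per-repeat ROC curves of an experiment
#'
#' @param object A `milcta_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.milcta_experiment <- function(object, ...) {
  df <- object$predictions %>%
    group_by(.data$repeat_id) %>%
    dplyr::group_modify(~ roc_points(.x$label, .x$prob)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   group = .data$repeat_id,
                                   colour = factor(.data$repeat_id))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Repeat",
                  title = sprintf("Patient-level ROC (mean AUC %.2f)",
                                  object$summary$mean_auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Calibration plot (patient-level)
#'
#' @param experiment A `milcta_experiment`.
#' @param n_bins Probability bins.
#' @return A ggplot object.
#' @export
plot_calibration <- function(experiment, n_bins = 10L) {
  tb <- calibration_table(experiment$predictions$label,
                          experiment$predictions$prob, n_bins)
  ggplot2::ggplot(tb, ggplot2::aes(.data$mean_predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed event fraction", size = "Cases",
                  title = "Calibration (pooled test predictions)") +
    ggplot2::theme_minimal()
}

#' Threshold-dependent metric plot
#'
#' @param experiment A `milcta_experiment`.
#' @param ... Passed to [threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(experiment, ...) {
  sw <- threshold_sweep(experiment$predictions$label,
                        experiment$predictions$prob, ...) %>%
    tidyr::pivot_longer(-"threshold", names_to = "metric")
  ggplot2::ggplot(sw, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Decision threshold", y = "Metric value",
                  colour = NULL, title = "Threshold-dependent metrics") +
    ggplot2::theme_minimal()
}

#' Case attention profile
#'
#' Bar chart of per-slice attention for one predicted case; plaque-bearing
#' slices (when ground truth is supplied) are highlighted.
#'
#' @param case A `milcta_case_prediction` from [predict_patient()].
#' @param truth Optional truth tibble for the patient (with `slice_index`
#'   and `has_plaque`); slice keys of `case` must be positions matching
#'   `truth` rows in order.
#' @return A ggplot object.
#' @export
plot_attention <- function(case, truth = NULL) {
  df <- tibble(slice = seq_along(case$case_attention) - 1L,
               attention = as.numeric(case$case_attention))
  if (!is.null(truth)) df$plaque <- truth$has_plaque[seq_len(nrow(df))]
  else df$plaque <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(.data$slice, .data$attention,
                                   fill = .data$plaque)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Slice index", y = "Attention (sums to 1)",
                  fill = "Plaque slice",
                  title = sprintf("Case attention (p = %.2f)",
                                  case$patient_prob)) +
    ggplot2::theme_minimal()
}
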