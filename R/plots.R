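#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve plot
#'
#' @param object A `bhsii_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bhsii_roc
#' @export
autoplot.bhsii_roc <- function(object, ...) {
  curve <- object$curve[order(object$curve$fpr, object$curve$sensitivity), ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Healing-trajectory plot of follow-up scores
#'
#' Median and interquartile band of each scale over the follow-up
#' timepoints.
#'
#' @param x A `bhsii_cohort`, `bhsii_validation` or [trajectory_summary()]
#'   tibble.
#' @param scales Scales to show (default: the five domains and the total).
#' @return A ggplot.
#' @export
plot_trajectory <- function(x, scales = c("pain", "stiffness", "function",
                                          "visual", "manual", "total")) {
  summary <- if (inherits(x, "bhsii_validation")) {
    x$summary
  } else if (inherits(x, "bhsii_cohort")) {
    trajectory_summary(x)
  } else {
    x
  }
  dat <- dplyr::filter(
    summary, .data$scale %in% scales,
    .data$timepoint %in% c("T0", "T1", "T3", "T6")
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$timepoint, y = .data$median, group = .data$scale
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(
      x = "Timepoint", y = "Normalized score (0-100)",
      title = "Median (IQR) follow-up scores"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object A `bhsii_cohort`.
#' @param ... Passed to [plot_trajectory()].
#' @method autoplot bhsii_cohort
#' @export
autoplot.bhsii_cohort <- function(object, ...) plot_trajectory(object, ...)
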