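#' Plot an ROC curve
#'
#' Step curve of sensitivity against false-positive rate over every score
#' cut-off, with the chance diagonal for reference.
#'
#' @param object A `cam_roc` tibble from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)", y = "Sensitivity",
      title = "ROC curve"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-cutoff diagnostic performance
#'
#' Forest-style display of sensitivity, specificity and predictive values
#' with their exact confidence intervals, faceted by population.
#'
#' @param object A `cam_accuracy` object from [cam_evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cam_accuracy <- function(object, ...) {
  long <- tidy(object) %>%
    filter(
      .data$block == "cutoff",
      .data$metric %in% c("sensitivity", "specificity", "ppv", "npv")
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$estimate, y = .data$level, colour = .data$metric)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.25, position = ggplot2::position_dodge(width = 0.6)
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$population)) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      x = "Estimate (exact 95% CI)", y = "Score cut-off", colour = NULL,
      title = "Diagnostic performance by cut-off"
    ) +
    ggplot2::theme_minimal()
}
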