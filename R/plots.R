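#' Plot a cut-off scan
#'
#' Hazard ratio and Wald p-value of the `hi >= c` split across the candidate
#' grid, the plot used to read off the optimal risk-group cut-off.
#'
#' @param object An `hi_cutoff_scan` from [scan_cutoffs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hi_cutoff_scan
#' @export
autoplot.hi_cutoff_scan <- function(object, ...) {
  df <- tidy(object)[tidy(object)$usable, , drop = FALSE]
  long <- tidyr::pivot_longer(
    df[c("cutoff", "hr", "p")], c("hr", "p"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity, levels = c("hr", "p"),
                          labels = c("hazard ratio", "p-value"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "candidate cut-off (health index)", y = NULL,
                  title = "Cut-off scan: univariate Cox splits") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `hi_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hi_roc
#' @export
autoplot.hi_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(unclass(object)),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("ROC: %s, %s (AUC = %.3f)",
                      attr(object, "score"), attr(object, "endpoint"),
                      attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a fitted Cox exposure model
#'
#' @param object An `hi_coxfit` from [fit_cox()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hi_coxfit
#' @export
autoplot.hi_coxfit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr, y = .data$level)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "hazard ratio (95% CI, log scale)", y = NULL,
      title = sprintf("%s mortality, %s model (ref: %s)",
                      object$endpoint,
                      if (object$adjusted) "adjusted" else "unadjusted",
                      object$reference)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of index values with risk-group boundaries
#'
#' @param data A data frame with an `hi` column (e.g. from
#'   [compute_health_index()]).
#' @param cutoffs An [risk_cutoffs()] object drawn as vertical lines.
#' @return A ggplot.
#' @export
plot_hi_distribution <- function(data, cutoffs = risk_cutoffs()) {
  check_columns(data, "hi", "data")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$hi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      xintercept = c(cutoffs$low_medium, cutoffs$medium_high),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "3-item health index", y = "subjects",
                  title = "Health index distribution with risk-group boundaries") +
    ggplot2::theme_minimal()
}
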