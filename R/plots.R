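#' Scatter of treatment effects with the weighted regression line
#'
#' One panel of the central-illustration style figure: surrogate log-ORs on
#' the x axis, final-endpoint log-ORs on the y axis, circle area proportional
#' to the number of randomized patients, and the patient-weighted fitted line.
#'
#' @param pairs `surrogacy_pairs` from [build_pairs()].
#' @param fit Optional `weighted_ls`; computed from `pairs` when `NULL`.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_surrogacy <- function(pairs, fit = NULL,
                           xlab = "log-OR, bleeding",
                           ylab = "log-OR, mortality") {
  if (is.null(fit)) fit <- weighted_regression(pairs)
  ggplot2::ggplot(as.data.frame(pairs),
                  ggplot2::aes(x = .data$x, y = .data$y, size = .data$w)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey55") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey55") +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "#B2182B") +
    ggplot2::geom_point(shape = 21, fill = "#2166AC", alpha = 0.55,
                        colour = "grey25") +
    ggplot2::scale_size_area(max_size = 12, guide = "none") +
    ggplot2::labs(x = xlab, y = ylab,
                  subtitle = sprintf("R² = %.2f (n = %d pairs)",
                                     fit$r2, fit$n)) +
    ggplot2::theme_minimal()
}

#' Funnel plot of per-comparison effects
#'
#' Standard error (inverted axis) against log effect, with the fixed-effect
#' centerline and 95% pseudo-confidence bounds.
#'
#' @param funnel Output of [funnel_data()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  center <- attr(funnel, "center")
  se_max <- max(funnel$se) * 1.05
  guide <- data.frame(se = seq(1e-6, se_max, length.out = 50))
  guide$lo <- center - .z975() * guide$se
  guide$hi <- center + .z975() * guide$se
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$log_effect, y = .data$se)) +
    ggplot2::geom_vline(xintercept = center, linetype = 2) +
    ggplot2::geom_line(data = guide, ggplot2::aes(x = .data$lo, y = .data$se),
                       linetype = 3, colour = "grey40") +
    ggplot2::geom_line(data = guide, ggplot2::aes(x = .data$hi, y = .data$se),
                       linetype = 3, colour = "grey40") +
    ggplot2::geom_point(shape = 21, fill = "grey70") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "log-OR", y = "standard error") +
    ggplot2::theme_minimal()
}
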