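#' Bland-Altman plot
#'
#' Differences against pair means with the bias and the 1.96-SD limits of
#' agreement as horizontal lines.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("Mean of predicted and observed %s",
                              object$units %||% ""),
                  y = "Predicted - observed",
                  title = sprintf("Bland-Altman: %s", object$metric_name)) +
    ggplot2::theme_minimal()
}

#' Regression-through-origin plot
#' @param object An [regression_through_origin()] result.
#' @param ... Unused.
#' @export
autoplot.origin_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = object$slope, intercept = 0, linewidth = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(title = sprintf("%s: predicted = %.4g x observed (R^2 = %.3f)",
                                  object$metric_name, object$slope, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Through-plane velocity map of a cross-section
#'
#' Scalar map of the through-plane velocity over the lumen lattice — the
#' per-level view used for eccentricity grading.
#'
#' @param section A [cross_section()] carrying velocities.
#' @export
plot_cross_section <- function(section) {
  sm <- section$samples[section$samples$lumen, ]
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$a, y = .data$b, fill = .data$v_through)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "v_through (m/s)") +
    ggplot2::labs(x = "in-plane u (mm)", y = "in-plane v (mm)") +
    ggplot2::theme_minimal()
}
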