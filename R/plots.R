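#' Plot methods
#'
#' `autoplot.stroke_suite()` shows training and cross-validated R-squared
#' per model; `autoplot.stroke_fit()` draws the residual Q-Q plot used for
#' the normality check; `plot_selection_path()` tracks R-squared along the
#' greedy selection steps.
#'
#' @param object A `stroke_suite` or `stroke_fit`.
#' @param path A `selection_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name strokeconn-plots
NULL

#' @rdname strokeconn-plots
#' @method autoplot stroke_suite
#' @export
autoplot.stroke_suite <- function(object, ...) {
  m <- tidyr::pivot_longer(
    dplyr::select(object$models, "model", "r_squared", "cv_r_squared"),
    cols = c("r_squared", "cv_r_squared"),
    names_to = "metric", values_to = "value"
  )
  m$model <- factor(m$model, levels = rev(object$models$model))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$value, y = .data$model,
                                  colour = .data$metric)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(r_squared = "grey30", cv_r_squared = "steelblue"),
      labels = c(r_squared = "training R²",
                 cv_r_squared = "cross-validated R²")
    ) +
    ggplot2::labs(x = "R²", y = NULL, colour = NULL,
                  title = "Severity model suite") +
    ggplot2::theme_minimal()
}

#' @rdname strokeconn-plots
#' @method autoplot stroke_fit
#' @export
autoplot.stroke_fit <- function(object, ...) {
  qq <- residual_normality_check(object)$qq
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$theoretical,
                                   y = .data$sample)) +
    ggplot2::geom_abline(slope = sd(object$residuals),
                         intercept = mean(object$residuals),
                         linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "theoretical quantiles", y = "residual quantiles",
                  title = "Residual Q-Q plot") +
    ggplot2::theme_minimal()
}

#' @rdname strokeconn-plots
#' @export
plot_selection_path <- function(path, ...) {
  stopifnot(inherits(path, "selection_path"))
  d <- tidy(path)
  long <- tidyr::pivot_longer(
    dplyr::select(d, "step", "r_squared", "cv_r_squared"),
    cols = c("r_squared", "cv_r_squared"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$step) +
    ggplot2::labs(x = "selection step", y = "R²", colour = NULL,
                  title = "Greedy forward selection") +
    ggplot2::theme_minimal()
}
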