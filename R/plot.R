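#' Plot a kinetics fit
#'
#' Scatter of the fitted data points (phase time versus mass-normalised
#' VO2) with the fitted delayed-exponential curve overlaid, and the 95%
#' bootstrap band when [bootstrap_fit()] has been run.
#'
#' @param fit A converged `kinetics_fit`.
#' @param curve_points Number of points used to draw the curve.
#' @return A ggplot object.
#' @export
plot_fit <- function(fit, curve_points = 400) {
  stopifnot(inherits(fit, "kinetics_fit"))
  if (!fit$converged) rlang::abort("cannot plot a non-converged fit")
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("plot_fit requires the ggplot2 package")
  }
  tg <- seq(min(fit$data$t), max(fit$data$t), length.out = curve_points)
  curve <- tibble(t = tg, vo2 = model_value(tg, fit$params))
  p <- ggplot2::ggplot(fit$data, ggplot2::aes(x = t, y = y)) +
    ggplot2::geom_point(alpha = 0.4, size = 1)
  if (!is.null(fit$bootstrap)) {
    band <- apply(fit$bootstrap, 1, function(cf) {
      if (anyNA(cf)) return(rep(NA_real_, length(tg)))
      model_value(tg, .coef_to_params(cf, fit$model, fit$direction))
    })
    qs <- apply(band, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    curve$lo <- qs[1, ]
    curve$hi <- qs[2, ]
    p <- p + ggplot2::geom_ribbon(
      data = curve,
      ggplot2::aes(x = t, ymin = lo, ymax = hi),
      inherit.aes = FALSE, alpha = 0.25, fill = "steelblue"
    )
  }
  p +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = t, y = vo2),
                       linewidth = 0.8, colour = "steelblue") +
    ggplot2::labs(
      x = "phase time (s)",
      y = expression(dot(V) * O[2] ~ (mL %.% kg^-1 %.% min^-1)),
      title = sprintf("%s %s-transient fit", fit$model, fit$direction)
    ) +
    ggplot2::theme_minimal()
}
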