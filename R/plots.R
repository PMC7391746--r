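#' Plot a growth-rate regression
#'
#' Scatter of annual growth rates against the predictor, labelled by year,
#' with the OLS line and its 95% confidence band.
#'
#' @param object A `growth_fit` with a predictor term.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  if (!"predictor" %in% names(object$data)) {
    abort("The null model has no predictor to plot against.")
  }
  xlab <- if (object$predictor_mode == "delta") {
    if (object$lag == 0) "Same-year change in predictor" else
      "Previous-year change in predictor"
  } else {
    "Predictor level"
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$predictor, y = .data$lambda)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "grey30", fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$year),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = xlab,
      y = expression(lambda[t] == ln ~ N[t] - ln ~ N[t - 1]),
      title = paste0("Growth-rate regression (", object$model_id, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a temperature-only density projection
#'
#' @param object A `density_projection` from [project_density()].
#' @param ... Unused.
#' @return A ggplot with the projected relative density and, when
#'   available, the slope-CI band.
#' @exportS3Method ggplot2::autoplot
autoplot.density_projection <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$year,
                                            y = .data$relative_density))
  if (all(c("band_lo", "band_hi") %in% names(object))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_lo, ymax = .data$band_hi),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "Year",
                  y = sprintf("Density relative to %d",
                              attr(object, "base_year")),
                  title = "Temperature-only population projection") +
    ggplot2::theme_minimal()
}

#' Plot the annual temperature index and its moving average
#'
#' @param index Tibble with `year`, `temp_c` and optionally `temp_ma_c`.
#' @return A ggplot: annual values as points/thin line, moving average as
#'   a heavier line.
#' @export
plot_temp_index <- function(index) {
  check_annual_series(index, "temp_c", arg = "index")
  p <- ggplot2::ggplot(index, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$temp_c), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$temp_c),
                        colour = "grey40", size = 1)
  if ("temp_ma_c" %in% names(index)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$temp_ma_c),
      linewidth = 1, na.rm = TRUE
    )
  }
  p +
    ggplot2::labs(x = "Year", y = "Summer temperature index (°C)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
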