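#' Stacked sensitivity plot
#'
#' Fig.-style stacked bars of normalised total-effect indices per spectral
#' band.
#'
#' @param object A `lai_sensitivity` tibble from [sobol_rtm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lai_sensitivity <- function(object, ...) {
  bands <- unique(object$band)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$band, levels = bands),
                               y = .data$st_norm, fill = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~rtm) +
    ggplot2::labs(x = "band", y = "normalised total-effect index",
                  fill = "parameter") +
    ggplot2::theme_minimal()
}

#' Reference time-series plot
#'
#' Per-plot calibrated LAI series with linear interpolation between field
#' visits.
#'
#' @param object A `reference_series` from [calibrate_tls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reference_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$date, .data$lai,
                                       colour = .data$plot)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day of year", y = expression(LAI ~ (m^2 ~ m^-2)),
                  colour = "plot") +
    ggplot2::theme_minimal()
}

#' Grid-results distribution plot
#'
#' Box plots of validation RMSE by the levels of one workflow feature.
#' Realisations above `trim` are trimmed from the display (never from
#' statistics).
#'
#' @param results `grid_results` tibble from [run_grid()].
#' @param feature Feature column to group by.
#' @param trim Display cut-off for extreme RMSE values.
#' @return A ggplot object.
#' @export
plot_grid_rmse <- function(results, feature = "mlra", trim = 10) {
  shown <- results[results$val_rmse <= trim, ]
  ggplot2::ggplot(shown,
                  ggplot2::aes(factor(.data[[feature]]), .data$val_rmse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = feature,
                  y = expression(validation ~ RMSE ~ (m^2 ~ m^-2))) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-reference series plot
#'
#' The combined multi-sensor LAI prediction of one realisation against the
#' interpolated reference.
#'
#' @param series Series tibble from a realisation result (columns `date`,
#'   `pred`, `ref`, `sensor`).
#' @return A ggplot object.
#' @export
plot_realisation_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$date)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ref),
                       colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$pred,
                                     shape = .data$sensor),
                        colour = "#2166ac") +
    ggplot2::labs(x = "day of year", y = expression(LAI ~ (m^2 ~ m^-2)),
                  shape = "sensor") +
    ggplot2::theme_minimal()
}

#' @rdname summarize_grid
#' @param x A `grid_results` tibble.
#' @param ... Unused.
#' @export
glance.grid_results <- function(x, ...) {
  tibble(
    n_realisations = nrow(x),
    best_rmse = min(x$val_rmse),
    median_rmse = median(x$val_rmse),
    worst_rmse = max(x$val_rmse),
    best_id = x$id[which.min(x$val_rmse)]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
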