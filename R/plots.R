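# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reconstructed elevation grid
#'
#' @param object an `elevation_grid`.
#' @param hills optional [detect_hills()] table overlaid as points.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot elevation_grid
#' @export
autoplot.elevation_grid <- function(object, hills = NULL, ...) {
  p <- ggplot2::ggplot(object$cells,
                       ggplot2::aes(.data$x_center, .data$y_center,
                                    fill = .data$median_elev)) +
    ggplot2::geom_tile(width = object$spec$bin_size,
                       height = object$spec$bin_size) +
    ggplot2::scale_fill_viridis_c(name = "elevation (m)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (!is.null(hills) && nrow(hills)) {
    p <- p + ggplot2::geom_point(
      data = hills, ggplot2::aes(.data$summit_x, .data$summit_y),
      inherit.aes = FALSE, shape = 17, colour = "red", size = 2)
  }
  p
}

#' Plot a utilization distribution with percent-volume contours
#'
#' @param object a `ud_surface`.
#' @param contours percent-volume contour levels to draw (default 50, 95).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ud_surface
#' @export
autoplot.ud_surface <- function(object, contours = c(50, 95), ...) {
  df <- expand.grid(x = object$x, y = object$y)
  df$density <- as.vector(object$z)
  breaks <- vapply(contours, function(p) ud_level(object, p), numeric(1))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$density),
                          breaks = breaks, colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Coefficient plot for a fitted stop/advance/activity model
#'
#' Point estimates with Wald 95% intervals, intercept omitted.
#'
#' @param object a `hill_glmm`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hill_glmm
#' @export
autoplot.hill_glmm <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term,
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (logit scale)", y = NULL)
}

#' Likelihood profile of the autocorrelation-term bandwidth
#'
#' @param ac the `ac` element of [run_advance_analysis()] (or any
#'   [fit_ac_sigma()] result).
#' @return a ggplot of log-likelihood against sigma (log scale).
#' @export
plot_ac_profile <- function(ac) {
  ggplot2::ggplot(ac$profile, ggplot2::aes(.data$sigma, .data$logLik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = ac$sigma, linetype = 2,
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "AC bandwidth sigma (min, log scale)",
                  y = "model log-likelihood")
}

#' Activity budgets by territory section
#'
#' @param budgets an [activity_budgets()] table.
#' @return a stacked-bar ggplot of percent time per section.
#' @export
plot_budgets <- function(budgets) {
  p <- ggplot2::ggplot(budgets,
                       ggplot2::aes(.data$section, .data$percent,
                                    fill = .data$activity)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of observation time")
  if ("group" %in% names(budgets)) {
    p <- p + ggplot2::facet_wrap(~group)
  }
  p
}
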