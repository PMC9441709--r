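# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a predicted noise surface
#'
#' @param object A `noise_surface`.
#' @param layer Which aggregate layer to map.
#' @param ... Unused.
#' @return A ggplot (raster map; masked cells blank).
#' @method autoplot noise_surface
#' @export
autoplot.noise_surface <- function(object, layer = "l_den", ...) {
  met <- object$metrics
  ggplot2::ggplot(met, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data[[layer]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(layer, " (dBA)"),
                                  option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted LUR model
#'
#' @param object A `lur_model`.
#' @param ... Unused.
#' @return A ggplot showing coefficients with 95% CIs.
#' @method autoplot lur_model
#' @export
autoplot.lur_model <- function(object, ...) {
  co <- object$coefficients
  co <- co[co$term != "(Intercept)", ]
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "coefficient (dBA)", y = NULL,
                  title = sprintf("LAeq_1hr %s model", object$period)) +
    ggplot2::theme_minimal()
}

#' Cumulative population exposure curve
#'
#' Share of the population living in enumeration areas below each noise
#' level, with guideline thresholds as vertical lines.
#'
#' @param summary An `exposure_summary`.
#' @return A ggplot.
#' @export
plot_exposure_cdf <- function(summary) {
  p <- ggplot2::ggplot(summary$cumulative,
                       ggplot2::aes(x = .data$level, y = .data$cum_pct,
                                    colour = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "EA-average level (dBA)",
                  y = "cumulative % of population") +
    ggplot2::theme_minimal()
  if (nrow(summary$exceedance) > 0) {
    p <- p + ggplot2::geom_vline(
      data = summary$exceedance,
      ggplot2::aes(xintercept = .data$threshold_dba, colour = .data$metric),
      linetype = 2)
  }
  p
}

#' Noise distribution across SES quintiles
#'
#' @param object A `ses_inequality`.
#' @param ... Unused.
#' @return A ggplot of per-quintile medians and IQRs.
#' @method autoplot ses_inequality
#' @export
autoplot.ses_inequality <- function(object, ...) {
  ggplot2::ggplot(object$quintiles,
                  ggplot2::aes(x = factor(.data$quintile), y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25,
                                          ymax = .data$q75)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = paste("quintile of", object$measure),
                  y = "EA-average level (dBA)") +
    ggplot2::theme_minimal()
}
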