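# ggplot2 layers for the standard diagnostic and simulation displays.

#' Goodness-of-fit panels
#'
#' Four standard panels from a [gof()] table: observations vs population
#' predictions, observations vs individual predictions, |iWRES| vs
#' individual predictions, and weighted residuals vs time.
#'
#' @param fit A [pk_fit()] result.
#' @return A ggplot object (faceted).
#' @export
plot_gof <- function(fit) {
  g <- gof(fit)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "Observed vs population predicted",
                   x = g$pred, y = g$obs),
    tibble::tibble(panel = "Observed vs individual predicted",
                   x = g$ipred, y = g$obs),
    tibble::tibble(panel = "|iWRES| vs individual predicted",
                   x = g$ipred, y = g$abs_iwres),
    tibble::tibble(panel = "WRES vs time",
                   x = g$time, y = g$wres)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "red") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a prediction-corrected visual predictive check
#'
#' Observed prediction-corrected percentiles (points/lines) over the
#' simulated 2.5-97.5 percentile band.
#'
#' @param object A [vpc()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vpc_result
#' @export
autoplot.vpc_result <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$t_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo, ymax = .data$sim_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_med), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_med)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_lo), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_hi), linetype = 2) +
    ggplot2::labs(x = "Time (h)",
                  y = "Prediction-corrected concentration (ng/ml)") +
    ggplot2::theme_bw()
}

#' Plot probability-of-target-attainment curves
#'
#' PTA vs dose, one line per weight, faceted by scenario.
#'
#' @param pta_table Output of [pta_grid()].
#' @return A ggplot object.
#' @export
plot_pta <- function(pta_table) {
  ggplot2::ggplot(pta_table,
                  ggplot2::aes(x = .data$dose_per_kg, y = 100 * .data$pta,
                               colour = factor(.data$weight))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(flu ~ regimen,
                        labeller = ggplot2::labeller(
                          flu = c(`0` = "no fluoxetine", `1` = "fluoxetine"),
                          regimen = c(qd = "once daily", bid = "twice daily"))) +
    ggplot2::labs(x = "Dose (mg/kg/day)", y = "PTA (%)",
                  colour = "Weight (kg)") +
    ggplot2::theme_bw()
}
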