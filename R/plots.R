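## ggplot2 visualisations for fitted calibrations, protocol runs and
## coefficient histories.

#' @export
autoplot.baps_ols <- function(object, ...) {
  pts <- object$points
  grid <- tibble(signal_v = seq(min(pts$signal_v), max(pts$signal_v),
                                length.out = 100))
  grid$fit <- object$a + object$b * grid$signal_v
  band <- object$t_crit * sqrt(object$sigma2) *
    sqrt(1 / object$k + (grid$signal_v - mean(pts$signal_v))^2 /
           sum((pts$signal_v - mean(pts$signal_v))^2))
  grid$lo <- grid$fit - band
  grid$hi <- grid$fit + band
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$signal_v, y = .data$measurand)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(x = .data$signal_v, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$signal_v, y = .data$fit),
                       inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "sensor signal (V)", y = "measurand",
      title = sprintf("y = %.4g + %.4g x   (R2 = %.5f, DW = %.2f)",
                      object$a, object$b, object$r_squared, object$dw)) +
    ggplot2::theme_minimal()
}

#' Residual plot of a calibration fit
#'
#' Residuals against the signal, for visual screening of non-linearity
#' or autocorrelation.
#'
#' @param fit A fitted `baps_ols`.
#' @return A ggplot object.
#' @export
plot_residuals <- function(fit) {
  stopifnot(inherits(fit, "baps_ols"))
  d <- tibble(signal_v = fit$points$signal_v, residual = fit$residuals)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signal_v, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sensor signal (V)", y = "residual",
                  title = sprintf("Durbin-Watson = %.2f", fit$dw)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration-coefficient history
#'
#' Dated intercept and slope series from repeated calibrations, faceted
#' by coefficient, for drift inspection.
#'
#' @param entries Data frame with `date`, `a`, `b`.
#' @return A ggplot object.
#' @export
plot_coefficient_history <- function(entries) {
  entries <- check_history(entries, min_n = 2)
  if (!"date" %in% names(entries)) {
    entries$date <- seq_len(nrow(entries))
  }
  long <- tidyr::pivot_longer(entries[c("date", "a", "b")],
                              cols = c("a", "b"),
                              names_to = "coefficient", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "coefficient value",
                  title = "repeated calibrations") +
    ggplot2::theme_minimal()
}

#' Plot the concentration staircase of an exchange protocol
#'
#' O2 and CO2 reference concentrations over the removal/injection steps.
#'
#' @param protocol A [baps_protocol()].
#' @return A ggplot object.
#' @export
plot_protocol <- function(protocol) {
  run <- run_protocol(protocol)
  long <- tidyr::pivot_longer(run[c("step", "o2_volpct", "co2_volpct")],
                              cols = -"step",
                              names_to = "species", values_to = "volpct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$volpct,
                                     colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "exchange step", y = "concentration (Vol%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
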