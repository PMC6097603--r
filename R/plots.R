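#' Kymograph plot of a rotor-chain trajectory
#'
#' Raster of `sin(phi_i)` over rotor index and time: metachronal waves
#' appear as diagonal stripes, phase defects as dislocations.
#'
#' @param object A `rotor_trajectory`.
#' @param t_max Optional upper time limit (s) to keep the raster readable.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rotor_trajectory <- function(object, t_max = NULL, ...) {
  df <- tidy(object)
  if (!is.null(t_max)) df <- dplyr::filter(df, .data$time <= t_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$rotor,
                                   fill = sin(.data$phi))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white", name = "sin(phi)") +
    ggplot2::scale_y_continuous(breaks = unique(df$rotor)) +
    ggplot2::labs(x = "time (s)", y = "rotor") +
    ggplot2::theme_minimal()
}

#' Phase-diagram plot of a sweep
#'
#' Tile map over `(h, lambda)` of a chosen summary: end-to-end drift per
#' beat, order-parameter amplitude or angle, or the regime label.
#'
#' @param object A `rotor_sweep` from [run_sweep()].
#' @param fill One of `"drift_per_beat"`, `"A_bar"`, `"Psi_bar_abs"`,
#'   `"label"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rotor_sweep <- function(object,
                                 fill = c("drift_per_beat", "A_bar",
                                          "Psi_bar_abs", "label"),
                                 ...) {
  fill <- match.arg(fill)
  ggplot2::ggplot(object, ggplot2::aes(.data$h * 1e6, .data$lambda * 1e6,
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "height h (um)", y = "stiffness lambda (pN/um)",
                  fill = fill) +
    ggplot2::theme_minimal()
}

#' Bifurcation plot of a pair scan
#'
#' Average phase drift versus detuning, overlaying theory and simulation
#' rows when both are present; the locked branch sits at zero drift up to
#' the critical detuning.
#'
#' @param object A `pair_scan` from [pair_bifurcation_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$D, .data$drift,
                                       colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "detuning D", y = "average drift (rad/s)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
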