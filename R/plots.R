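#' Plot bump transfer curves over a grid of width-control voltages
#'
#' @param d A [device_model()].
#' @param vc Width-control voltages to draw.
#' @param i_bias Bias current, amperes.
#' @param v_r Center voltage.
#' @return A ggplot.
#' @export
plot_bump_response <- function(d = device_model(),
                               vc = c(-0.1, 0, 0.1),
                               i_bias = 12e-9, v_r = 0) {
  df <- purrr::map_dfr(vc, function(v) {
    p <- bump_params(v_r = v_r, v_c = v, i_bias = i_bias)
    v_in <- seq(d$supply_neg, d$supply_pos, length.out = 401)
    tibble::tibble(v_c = v, v_in = v_in,
                   current = bump_current(v_in, p, d))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$v_in, .data$current * 1e9,
                                   colour = factor(.data$v_c))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Input voltage (V)", y = "Output current (nA)",
                  colour = "Vc (V)") +
    ggplot2::theme_minimal()
}

#' Alarm raster over the record timeline
#'
#' Ictal-state bands with the raised alarms overlaid, one record per panel
#' when a `patient` column is present.
#'
#' @param windows Scored windows with `t_start`, `state` and `alarm`.
#' @return A ggplot.
#' @export
plot_alarm_raster <- function(windows) {
  df <- dplyr::mutate(windows, hours = .data$t_start / 3600)
  ggplot2::ggplot(df, ggplot2::aes(.data$hours, y = 1)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$state), height = 0.6) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$alarm),
      ggplot2::aes(y = 1.45), shape = "|", size = 3, colour = "black"
    ) +
    ggplot2::scale_fill_manual(values = c(
      inter_ictal = "#9ecae1", pre_ictal = "#fd8d3c",
      ictal = "#de2d26", post_ictal = "#c7e9c0"
    )) +
    ggplot2::labs(x = "Time (h)", y = NULL, fill = "State") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Histogram of Monte-Carlo specificities
#'
#' @param object An `mc_result` from [monte_carlo_eval()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_result <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(100 * .data$specificity)) +
    ggplot2::geom_histogram(bins = 20, fill = "#3182bd",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 100 * object$mean,
                        linetype = "dashed") +
    ggplot2::labs(x = "Specificity (%)", y = "Runs") +
    ggplot2::theme_minimal()
}

#' Width calibration curve
#'
#' @param object A `width_calibration` from [calibrate_width()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.width_calibration <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$v_c, 1e3 * .data$sigma)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Vc (V)", y = "Effective sigma (mV)") +
    ggplot2::theme_minimal()
}

#' System power versus front-end specificity
#'
#' @param object An `accounting_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accounting_report <- function(object, ...) {
  ggplot2::ggplot(object$power_sweep,
                  ggplot2::aes(.data$specificity, 1e6 * .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wake-up specificity",
                  y = "Total system power (µW)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
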