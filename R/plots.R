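# autoplot() methods: quick diagnostic figures for each result type.

#' @export
autoplot.harmonic_spectrum <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$frequency_hz, y = 2 * .data$coefficient_a)
  ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency_hz, yend = 0)) +
    ggplot2::labs(
      x = "frequency (Hz)", y = "single-sided amplitude (A)",
      title = "Analytic harmonic amplitudes"
    )
}

#' @export
autoplot.amplitude_spectrum <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$frequency_hz, y = .data$amplitude_a)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "frequency (Hz)", y = "amplitude (A)",
      title = "Single-sided FFT amplitude spectrum"
    )
}

#' @export
autoplot.impedance_spectrum <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$z_real_ohm, y = -.data$z_imag_ohm)
  ) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Re Z (ohm)", y = "-Im Z (ohm)",
      title = "Impedance locus (Nyquist plot)"
    )
}

#' @export
autoplot.rrc_fit <- function(object, n_points = 200, ...) {
  f_rng <- range(object$data$frequency_hz)
  model <- spectrum_from_circuit(
    object$circuit,
    frequency_hz = 10^seq(log10(f_rng[1]), log10(f_rng[2]), length.out = n_points)
  )
  ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$z_real_ohm, y = -.data$z_imag_ohm)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = model, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Re Z (ohm)", y = "-Im Z (ohm)",
      title = "R-RC circuit fit",
      subtitle = sprintf(
        "Rs = %.0f ohm, Rp = %.0f ohm, Cp = %.0f nF; |Z(1 kHz)| = %.0f ohm",
        object$circuit$rs_ohm, object$circuit$rp_ohm,
        object$circuit$cp_f * 1e9, object$z1k_ohm
      )
    )
}

#' @export
autoplot.adaptive_solution <- function(object, ...) {
  ggplot2::ggplot(
    object$trace,
    ggplot2::aes(x = .data$iteration, y = .data$impedance_ohm)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "Picard iteration", y = "terminal impedance (ohm)",
      title = "Adaptive-conductivity convergence"
    )
}

#' Plot the field-to-conductivity transfer function
#'
#' @param tf A [transfer_function_params()].
#' @param scalp A [scalp_params()].
#' @param max_field Upper plot limit (V/m); default 1.5x the saturation
#'   field.
#' @return A ggplot object.
#' @export
plot_sigma_ss <- function(tf = transfer_function_params(),
                          scalp = scalp_params(0.002, 0.16),
                          max_field = NULL) {
  max_field <- max_field %||% (1.5 * scalp$saturation_field)
  grid <- tibble(field_v_m = seq(0, max_field, length.out = 600))
  grid$sigma_s_m <- sigma_ss(grid$field_v_m, tf, scalp)
  ggplot2::ggplot(
    grid, ggplot2::aes(x = .data$field_v_m, y = .data$sigma_s_m)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      xintercept = c(tf$field_threshold, scalp$saturation_field),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "local electric field (V/m)",
      y = "superficial-scalp conductivity (S/m)",
      title = "Adaptive scalp conductivity transfer function"
    )
}
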