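#' Specify an alternating-polarity rectangular pulse train
#'
#' ECT devices deliver current-controlled trains of rectangular pulses with
#' alternating polarity: within each full cycle of period `period`, the
#' current is `+amplitude` on `[0, pulse_width)`, `-amplitude` on
#' `[period/2, period/2 + pulse_width)`, and zero elsewhere. A clinical
#' "0.5 ms at 20 Hz" dose maps to `pulse_width = 5e-4`, `period = 0.05`
#' (the period of one full +/- cycle; see Details).
#'
#' @details The cycle-rate convention: the repetition frequency `1/period`
#'   counts full alternating cycles, each containing one positive and one
#'   negative pulse. Devices sometimes quote pulses per second, which is
#'   twice this rate; callers quoting pulse rate should halve it when
#'   building a spec.
#'
#' @param amplitude Peak current in amperes (A), > 0.
#' @param pulse_width Width of each rectangular pulse in seconds; must
#'   satisfy `0 < pulse_width <= period / 2`.
#' @param period Duration of one full alternating cycle in seconds.
#' @param duration Total record length in seconds, at least one period.
#' @param sample_rate Sampling rate in Hz; at least `20 / pulse_width` so
#'   that pulse edges are resolved.
#'
#' @return An object of class `pulse_train_spec`.
#' @seealso [generate_pulse_train()], [analytic_harmonics()],
#'   [square_wave_spec()]
#' @examples
#' pulse_train_spec(
#'   amplitude = 0.9, pulse_width = 5e-4, period = 0.05,
#'   duration = 1, sample_rate = 1e5
#' )
#' @export
pulse_train_spec <- function(amplitude, pulse_width, period, duration,
                             sample_rate) {
  check_scalar_positive(amplitude, "amplitude")
  check_scalar_positive(pulse_width, "pulse_width")
  check_scalar_positive(period, "period")
  check_scalar_positive(duration, "duration")
  check_scalar_positive(sample_rate, "sample_rate")
  if (pulse_width > period / 2) {
    stop_invalid(
      "`pulse_width` must not exceed `period / 2`: the positive and negative pulses must both fit in one cycle."
    )
  }
  if (sample_rate < 20 / pulse_width) {
    stop_invalid(
      sprintf(
        "`sample_rate` must be at least 20 / pulse_width (= %g Hz) to resolve pulse edges.",
        20 / pulse_width
      )
    )
  }
  if (duration < period) {
    stop_invalid("`duration` must cover at least one full period.")
  }
  structure(
    list(
      amplitude = amplitude, pulse_width = pulse_width, period = period,
      duration = duration, sample_rate = sample_rate
    ),
    class = "pulse_train_spec"
  )
}

#' @export
print.pulse_train_spec <- function(x, ...) {
  cat("<pulse_train_spec>\n")
  cat(sprintf(
    "  amplitude: %g A, pulse width: %g ms, period: %g ms (%g Hz cycle rate)\n",
    x$amplitude, x$pulse_width * 1e3, x$period * 1e3, 1 / x$period
  ))
  cat(sprintf(
    "  duration: %g s at %g Hz sampling\n", x$duration, x$sample_rate
  ))
  invisible(x)
}

#' Specify a biphasic square-wave test signal
#'
#' The degenerate pulse train with `pulse_width = period / 2` (no off time),
#' i.e. a square wave. ECT devices probe static impedance with a low-current
#' high-frequency test signal well modeled as a biphasic square wave; the
#' defaults give the ~800 Hz, 2 uA test waveform.
#'
#' @param amplitude Peak current (A). Default 2e-6.
#' @param frequency Square-wave frequency in Hz. Default 800.
#' @param duration Record length (s). Default 0.5.
#' @param sample_rate Sampling rate (Hz); default `8e4 * frequency / 800`
#'   keeps 100 samples per cycle.
#' @return A [pulse_train_spec()].
#' @export
square_wave_spec <- function(amplitude = 2e-6, frequency = 800,
                             duration = 0.5,
                             sample_rate = 100 * frequency) {
  check_scalar_positive(frequency, "frequency")
  pulse_train_spec(
    amplitude = amplitude, pulse_width = 1 / (2 * frequency),
    period = 1 / frequency, duration = duration, sample_rate = sample_rate
  )
}

#' Sample a pulse train in the time domain
#'
#' Evaluates the alternating-polarity pulse train on a uniform time grid
#' `t = 0, 1/fs, 2/fs, ...` covering `duration`. Pulse edges follow
#' half-open intervals `[start, start + pulse_width)`: a sample landing
#' exactly on a falling edge takes the post-edge value.
#'
#' @param spec A [pulse_train_spec()].
#' @return A tibble of class `sampled_signal` with columns `time_s` and
#'   `current_a`, and a `sample_rate` attribute.
#' @examples
#' sig <- generate_pulse_train(pulse_train_spec(0.9, 5e-4, 0.05, 0.1, 1e5))
#' mean(sig$current_a) # zero-mean biphasic train
#' @export
generate_pulse_train <- function(spec) {
  if (!inherits(spec, "pulse_train_spec")) {
    stop_invalid("`spec` must be created with pulse_train_spec().")
  }
  # half-open record [0, duration): an integer number of periods is sampled
  # without a duplicated endpoint, keeping the train exactly zero-mean
  n <- max(2L, round(spec$duration * spec$sample_rate))
  t <- (seq_len(n) - 1L) / spec$sample_rate
  phase <- t %% spec$period
  # floating error in %% can park a period-start sample epsilon below the
  # period; fold it back, and compare edges with the same tolerance
  eps <- 1e-9 * spec$period
  phase[phase >= spec$period - eps] <- 0
  v <- numeric(n)
  v[phase < spec$pulse_width - eps] <- spec$amplitude
  neg <- phase >= spec$period / 2 - eps &
    phase < spec$period / 2 + spec$pulse_width - eps
  v[neg] <- -spec$amplitude
  out <- tibble(time_s = t, current_a = v)
  attr(out, "sample_rate") <- spec$sample_rate
  class(out) <- c("sampled_signal", class(out))
  out
}

#' Analytic amplitude spectrum of a pulse train
#'
#' The two-sided Fourier-coefficient magnitudes of the alternating-polarity
#' pulse train are
#' \deqn{|C_n| = \frac{A}{\pi n}\,\left|\sin\!\left(\frac{\pi n \Delta}{T}\right)\right|\,(1 - (-1)^n),}
#' with amplitude \eqn{A}, pulse width \eqn{\Delta} and period \eqn{T}.
#' Every even harmonic vanishes (the two half-cycles cancel), and the
#' \eqn{\sin} envelope has its first null at frequency \eqn{1/\Delta}.
#' A single-sided measured spectrum carries `2 * coefficient_a` at each
#' harmonic (see [numeric_spectrum()]).
#'
#' @param spec A [pulse_train_spec()].
#' @param n_max Highest harmonic index to evaluate (>= 1).
#' @return A tibble of class `harmonic_spectrum` with columns `harmonic`
#'   (n), `frequency_hz` (n / period) and `coefficient_a` (the magnitude
#'   |Cn| in amperes).
#' @examples
#' spec <- pulse_train_spec(0.9, 5e-4, 0.05, 1, 1e5)
#' analytic_harmonics(spec, n_max = 5)
#' @export
analytic_harmonics <- function(spec, n_max) {
  if (!inherits(spec, "pulse_train_spec")) {
    stop_invalid("`spec` must be created with pulse_train_spec().")
  }
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1) {
    stop_invalid("`n_max` must be a single integer >= 1.")
  }
  n <- seq_len(floor(n_max))
  cn <- spec$amplitude / (pi * n) *
    abs(sin(pi * n * spec$pulse_width / spec$period)) * (1 - (-1)^n)
  out <- tibble(
    harmonic = as.integer(n),
    frequency_hz = n / spec$period,
    coefficient_a = cn
  )
  class(out) <- c("harmonic_spectrum", class(out))
  out
}

#' Single-sided FFT amplitude spectrum of a sampled signal
#'
#' Computes the discrete Fourier transform and folds it to a single-sided
#' amplitude spectrum, normalized so that a pure sinusoid of peak amplitude
#' `a` shows amplitude `a` in its frequency bin. Frequency resolution is
#' the reciprocal of the record length. To compare with
#' [analytic_harmonics()], note the single-sided amplitude at harmonic `n`
#' equals `2 * coefficient_a` (positive and negative frequency halves
#' fold together); leakage is avoided by sampling an integer number of
#' periods, so no window is applied.
#'
#' @param signal A tibble with `time_s` (uniformly spaced) and `current_a`
#'   columns, e.g. from [generate_pulse_train()].
#' @return A tibble of class `amplitude_spectrum` with columns
#'   `frequency_hz` (ascending, from 0) and `amplitude_a`.
#' @export
numeric_spectrum <- function(signal) {
  if (!all(c("time_s", "current_a") %in% names(signal))) {
    stop_invalid("`signal` needs columns `time_s` and `current_a`.")
  }
  t <- signal$time_s
  x <- signal$current_a
  n <- length(x)
  if (n < 2L) stop_invalid("`signal` must contain at least 2 samples.")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1] + 1e-15)) {
    stop_invalid("`signal` must be uniformly sampled.")
  }
  fs <- 1 / dt[1]
  x_hat <- fft(x) / n
  n_keep <- floor(n / 2) + 1L
  amp <- Mod(x_hat[seq_len(n_keep)])
  # fold negative frequencies onto positive ones (skip DC and, for even n,
  # the Nyquist bin, which have no mirror)
  fold <- 2:(n_keep - if (n %% 2L == 0L) 1L else 0L)
  amp[fold] <- 2 * amp[fold]
  out <- tibble(
    frequency_hz = (seq_len(n_keep) - 1L) * fs / n,
    amplitude_a = amp
  )
  class(out) <- c("amplitude_spectrum", class(out))
  out
}

#' First null of the pulse-width spectral envelope
#'
#' The harmonic magnitudes of a rectangular pulse train follow a
#' `sin(pi * n * pulse_width / period)` envelope whose first zero sits at
#' frequency `1 / pulse_width`: the main spectral lobe of a 0.5 ms pulse
#' ends at 2 kHz, of a 0.25 ms pulse at 4 kHz. The pulse repetition rate
#' and the pulse width thus bound the main-lobe content from below and
#' above.
#'
#' @param spec A [pulse_train_spec()].
#' @return The envelope-null frequency in Hz.
#' @examples
#' first_envelope_null(pulse_train_spec(0.9, 5e-4, 0.05, 1, 1e5)) # 2000 Hz
#' @export
first_envelope_null <- function(spec) {
  if (!inherits(spec, "pulse_train_spec")) {
    stop_invalid("`spec` must be created with pulse_train_spec().")
  }
  1 / spec$pulse_width
}
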