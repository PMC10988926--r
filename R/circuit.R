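#' Series + parallel R-RC lumped circuit
#'
#' The minimal lumped model of electrode-body impedance at low current: a
#' series (access) resistance `rs_ohm` in series with a parallel
#' resistor-capacitor pair (`rp_ohm`, `cp_f`). Its impedance is purely real
#' `rs + rp` at DC (capacitor open) and tends to `rs` at high frequency
#' (capacitor short); in between the real/imaginary locus traces a
#' semicircular arc of radius `rp / 2`.
#'
#' @param rs_ohm Series resistance in ohms, > 0.
#' @param rp_ohm Parallel resistance in ohms, > 0.
#' @param cp_f Parallel capacitance in farads, > 0.
#' @return An object of class `rrc_circuit`.
#' @examples
#' rrc_circuit(rs_ohm = 522, rp_ohm = 9890, cp_f = 175e-9)
#' @export
rrc_circuit <- function(rs_ohm, rp_ohm, cp_f) {
  check_scalar_positive(rs_ohm, "rs_ohm")
  check_scalar_positive(rp_ohm, "rp_ohm")
  check_scalar_positive(cp_f, "cp_f")
  structure(
    list(rs_ohm = rs_ohm, rp_ohm = rp_ohm, cp_f = cp_f),
    class = "rrc_circuit"
  )
}

#' @export
print.rrc_circuit <- function(x, ...) {
  cat(sprintf(
    "<rrc_circuit> Rs = %.4g ohm, Rp = %.4g ohm, Cp = %.4g nF  (|Z| at 1 kHz: %.0f ohm)\n",
    x$rs_ohm, x$rp_ohm, x$cp_f * 1e9, magnitude_at_1khz(x)
  ))
  invisible(x)
}

#' Complex impedance of an R-RC circuit
#'
#' \deqn{Z(f) = R_s + \frac{R_p}{1 + j\,2\pi f R_p C_p}}
#' At `f = 0` the exact DC limit `rs + rp` is returned.
#'
#' @param circuit An [rrc_circuit()].
#' @param frequency_hz Frequencies in Hz (vectorized), all >= 0.
#' @return Complex impedance(s) in ohms.
#' @export
circuit_impedance <- function(circuit, frequency_hz) {
  if (!inherits(circuit, "rrc_circuit")) {
    stop_invalid("`circuit` must be created with rrc_circuit().")
  }
  if (!is.numeric(frequency_hz) || any(!is.finite(frequency_hz)) ||
    any(frequency_hz < 0)) {
    stop_invalid("`frequency_hz` must be finite and non-negative.")
  }
  z <- circuit$rs_ohm +
    circuit$rp_ohm /
      (1 + 1i * 2 * pi * frequency_hz * circuit$rp_ohm * circuit$cp_f)
  z[frequency_hz == 0] <- complex(real = circuit$rs_ohm + circuit$rp_ohm)
  z
}

#' Impedance magnitude at 1 kHz
#'
#' The representative-frequency summary of a fitted circuit: `|Z(1 kHz)|`.
#' 1 kHz sits inside the main spectral lobe of clinical stimulus pulse
#' trains and tracks device-reported impedances, which is what makes it the
#' modeling frequency of choice.
#'
#' @param circuit An [rrc_circuit()].
#' @param round_ohm Round half-away-from-zero to integer ohms (default
#'   FALSE).
#' @return Magnitude in ohms.
#' @examples
#' magnitude_at_1khz(rrc_circuit(522, 9890, 175e-9), round_ohm = TRUE) # 1086
#' @export
magnitude_at_1khz <- function(circuit, round_ohm = FALSE) {
  check_flag(round_ohm, "round_ohm")
  m <- Mod(circuit_impedance(circuit, 1000))
  if (round_ohm) round_half_up(m) else m
}

#' Build an impedance-spectrum table
#'
#' An impedance spectrum is a tibble with columns `frequency_hz`,
#' `z_real_ohm`, `z_imag_ohm`; rows are sorted ascending in frequency.
#' Frequencies must be positive and distinct, real parts positive.
#'
#' @param frequency_hz Frequencies (Hz).
#' @param impedance Complex impedances (ohm), or NULL if `z_real_ohm` /
#'   `z_imag_ohm` are given.
#' @param z_real_ohm,z_imag_ohm Real/imaginary parts (ohm), alternative to
#'   `impedance`.
#' @return A tibble of class `impedance_spectrum`.
#' @seealso [spectrum_from_circuit()], [load_spectrum()]
#' @export
impedance_spectrum <- function(frequency_hz, impedance = NULL,
                               z_real_ohm = NULL, z_imag_ohm = NULL) {
  if (!is.null(impedance)) {
    z_real_ohm <- Re(impedance)
    z_imag_ohm <- Im(impedance)
  }
  if (is.null(z_real_ohm) || is.null(z_imag_ohm)) {
    stop_invalid("Provide `impedance` or both `z_real_ohm` and `z_imag_ohm`.")
  }
  if (length(frequency_hz) != length(z_real_ohm) ||
    length(frequency_hz) != length(z_imag_ohm)) {
    stop_invalid("Frequency and impedance vectors must have equal length.")
  }
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop_invalid("`frequency_hz` must be positive and finite.")
  }
  if (anyDuplicated(frequency_hz)) {
    stop_invalid("`frequency_hz` must be strictly ascending (no duplicates).")
  }
  if (any(z_real_ohm <= 0)) {
    stop_invalid("`z_real_ohm` must be positive (passive system).")
  }
  ord <- order(frequency_hz)
  out <- tibble(
    frequency_hz = frequency_hz[ord],
    z_real_ohm = z_real_ohm[ord],
    z_imag_ohm = z_imag_ohm[ord]
  )
  class(out) <- c("impedance_spectrum", class(out))
  out
}

#' Synthesize the spectrum of a known circuit
#'
#' Evaluates [circuit_impedance()] on a frequency grid and returns it as an
#' [impedance_spectrum()] table; convenient for round-trip tests and for
#' overlaying fits on data.
#'
#' @param circuit An [rrc_circuit()].
#' @param frequency_hz Frequencies (Hz), default 30 log-spaced points over
#'   10 Hz - 1 kHz (the usual measurement span).
#' @return An [impedance_spectrum()] tibble.
#' @export
spectrum_from_circuit <- function(circuit,
                                  frequency_hz = 10^seq(1, 3, length.out = 30)) {
  z <- circuit_impedance(circuit, frequency_hz)
  impedance_spectrum(frequency_hz, impedance = z)
}

#' Fit an R-RC circuit to an impedance spectrum
#'
#' Least-squares fit of the [rrc_circuit()] model to measured complex
#' impedance, minimizing the sum of squared real-part plus squared
#' imaginary-part errors (unweighted, in ohms) with the
#' Levenberg-Marquardt algorithm. Measured electrode-skin spectra deviate
#' from the R-RC arc at low frequency (both real and imaginary parts rise
#' in a way the single-dispersion model cannot capture), so only points
#' with `frequency_hz > frequency_floor_hz` are used.
#'
#' The fit is deterministic: parameters are log-transformed (keeping them
#' positive without constraints) and started from a fixed rule — `rs` from
#' the highest-frequency real part, `rp` from the low-frequency real part
#' minus `rs`, and `cp` from the frequency of the most negative imaginary
#' part via `2 * pi * f * rp * cp = 1`.
#'
#' @param spectrum An [impedance_spectrum()] tibble (or any data frame with
#'   its columns).
#' @param frequency_floor_hz Retain only points strictly above this
#'   frequency (default 100).
#' @param max_iter Levenberg-Marquardt iteration cap (default 200).
#' @return An object of class `rrc_fit`: a list with elements `circuit`
#'   ([rrc_circuit()]), `residual_norm` (ohms), `n_points_used`,
#'   `frequency_floor_hz`, `z1k_ohm` and `data` (the retained points).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' truth <- rrc_circuit(500, 1e4, 150e-9)
#' fit <- fit_rrc(spectrum_from_circuit(truth))
#' glance(fit)
#' @export
fit_rrc <- function(spectrum, frequency_floor_hz = 100, max_iter = 200) {
  req <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  missing_cols <- setdiff(req, names(spectrum))
  if (length(missing_cols)) {
    stop_invalid(sprintf(
      "`spectrum` is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (frequency_floor_hz < 0) {
    stop_invalid("`frequency_floor_hz` must be >= 0.")
  }
  keep <- spectrum$frequency_hz > frequency_floor_hz
  pts <- spectrum[keep, req]
  pts <- pts[order(pts$frequency_hz), ]
  if (nrow(pts) < 3L) {
    stop_invalid(sprintf(
      "Need at least 3 spectrum points above %g Hz; found %d.",
      frequency_floor_hz, nrow(pts)
    ))
  }

  f <- pts$frequency_hz
  z_obs <- complex(real = pts$z_real_ohm, imaginary = pts$z_imag_ohm)

  # deterministic initialization from the arc's asymptotes
  rs0 <- max(pts$z_real_ohm[which.max(f)], 1e-3)
  rp0 <- max(pts$z_real_ohm[which.min(f)] - rs0, rs0 * 0.1, 1e-3)
  f_peak <- f[which.min(pts$z_imag_ohm)]
  cp0 <- 1 / (2 * pi * f_peak * rp0)

  resid_fun <- function(logp) {
    p <- exp(logp)
    zm <- p[1] + p[2] / (1 + 1i * 2 * pi * f * p[2] * p[3])
    c(Re(zm) - Re(z_obs), Im(zm) - Im(z_obs))
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(rs0, rp0, cp0)), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-14, ptol = 1e-14)
  )
  p <- exp(fit$par)
  circuit <- rrc_circuit(p[1], p[2], p[3])
  rnorm_ohm <- sqrt(fit$deviance)
  if (fit$info == 5L) {
    stop_invalid(
      sprintf(
        "Levenberg-Marquardt did not converge in %d iterations (best so far: Rs=%.4g, Rp=%.4g, Cp=%.4g, residual %.4g ohm).",
        max_iter, p[1], p[2], p[3], rnorm_ohm
      ),
      class = "ectfield_convergence_error",
      circuit = circuit, residual_norm = rnorm_ohm
    )
  }
  structure(
    list(
      circuit = circuit,
      residual_norm = rnorm_ohm,
      n_points_used = nrow(pts),
      frequency_floor_hz = frequency_floor_hz,
      z1k_ohm = magnitude_at_1khz(circuit),
      data = impedance_spectrum(f, impedance = z_obs)
    ),
    class = "rrc_fit"
  )
}

#' @export
print.rrc_fit <- function(x, ...) {
  cat("<rrc_fit>\n  ")
  print(x$circuit)
  cat(sprintf(
    "  %d points above %g Hz, residual norm %.3g ohm\n",
    x$n_points_used, x$frequency_floor_hz, x$residual_norm
  ))
  invisible(x)
}

#' Read / write impedance spectra as CSV
#'
#' CSV with header `frequency_hz,z_real_ohm,z_imag_ohm`. Rows are sorted
#' ascending in frequency on load; malformed rows or missing columns raise
#' an error naming the problem (with the offending line for bad rows).
#'
#' @param path File path.
#' @return `load_spectrum()` returns an [impedance_spectrum()];
#'   `save_spectrum()` returns `path` invisibly.
#' @export
load_spectrum <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("No such file: %s", path))
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_double())
  )
  req <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop_invalid(sprintf(
      "Spectrum file %s is missing column(s): %s.",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- which(!stats::complete.cases(raw[req]))
  if (length(bad)) {
    stop_invalid(sprintf(
      "Malformed spectrum row(s) in %s at data line(s): %s.",
      path, paste(head(bad, 5), collapse = ", ")
    ))
  }
  impedance_spectrum(raw$frequency_hz,
    z_real_ohm = raw$z_real_ohm, z_imag_ohm = raw$z_imag_ohm
  )
}

#' @rdname load_spectrum
#' @param spectrum An [impedance_spectrum()] tibble.
#' @export
save_spectrum <- function(spectrum, path) {
  req <- c("frequency_hz", "z_real_ohm", "z_imag_ohm")
  missing_cols <- setdiff(req, names(spectrum))
  if (length(missing_cols)) {
    stop_invalid(sprintf(
      "`spectrum` is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  readr::write_csv(spectrum[req], path)
  invisible(path)
}
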