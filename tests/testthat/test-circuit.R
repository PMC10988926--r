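test_that("circuit impedance hits its DC and high-frequency limits", {
  circ <- rrc_circuit(500, 1e4, 150e-9)
  expect_equal(circuit_impedance(circ, 0), 10500 + 0i)
  expect_equal(Re(circuit_impedance(circ, 1e9)), 500, tolerance = 1e-4)
  expect_lt(abs(Im(circuit_impedance(circ, 1e9))), 1)
  # Cp -> 0 limit is frequency independent
  flat <- rrc_circuit(500, 1e4, 1e-18)
  expect_equal(Mod(circuit_impedance(flat, 1e3)), 10500, tolerance = 1e-9)
  expect_error(circuit_impedance(circ, -1), class = "ectfield_error")
})

test_that("1 kHz magnitudes reproduce the reference subject fits", {
  fits <- eis_subject_fits()
  z <- vapply(
    seq_len(nrow(fits)),
    function(i) {
      magnitude_at_1khz(
        rrc_circuit(fits$rs_ohm[i], fits$rp_ohm[i], fits$cp_f[i]),
        round_ohm = TRUE
      )
    },
    numeric(1)
  )
  consistent <- fits$z1k_consistent
  expect_true(all(
    abs(z[consistent] - fits$z1k_reported_ohm[consistent]) <=
      0.01 * fits$z1k_reported_ohm[consistent]
  ))
  # the flagged row is genuinely inconsistent, not a tolerance issue
  expect_gt(
    abs(z[!consistent] - fits$z1k_reported_ohm[!consistent]),
    0.1 * fits$z1k_reported_ohm[!consistent]
  )
})

test_that("|Z| is non-increasing in frequency and traces the R-RC arc", {
  for (circ in list(
    rrc_circuit(500, 1e4, 150e-9),
    rrc_circuit(372, 2840, 294e-9),
    rrc_circuit(50, 5e5, 1e-6)
  )) {
    f <- 10^seq(0, 5, length.out = 400)
    z <- circuit_impedance(circ, f)
    expect_true(all(diff(Mod(z)) <= 1e-9))
    # (Re - Rs - Rp/2)^2 + Im^2 = (Rp/2)^2
    arc <- (Re(z) - circ$rs_ohm - circ$rp_ohm / 2)^2 + Im(z)^2
    expect_equal(arc, rep((circ$rp_ohm / 2)^2, length(f)), tolerance = 1e-9)
  }
})

test_that("fitting recovers a known circuit from its own noiseless spectrum", {
  truth <- rrc_circuit(500, 1e4, 150e-9)
  spec <- spectrum_from_circuit(
    truth,
    frequency_hz = 10^seq(2, 3, length.out = 20)
  )
  fit <- fit_rrc(spec)
  expect_equal(fit$circuit$rs_ohm, 500, tolerance = 1e-3)
  expect_equal(fit$circuit$rp_ohm, 1e4, tolerance = 1e-3)
  expect_equal(fit$circuit$cp_f, 150e-9, tolerance = 1e-3)
  expect_lt(fit$residual_norm, 1e-6)
  # idempotence: refitting the model of the fit returns the same circuit
  refit <- fit_rrc(spectrum_from_circuit(fit$circuit, spec$frequency_hz))
  expect_equal(refit$circuit$rp_ohm, fit$circuit$rp_ohm, tolerance = 1e-3)
})

test_that("fitting tolerates 1% multiplicative noise (fixed seed)", {
  truth <- rrc_circuit(500, 1e4, 150e-9)
  f <- 10^seq(2, 3, length.out = 20)
  z <- circuit_impedance(truth, f)
  withr::with_seed(42, {
    z_noisy <- complex(
      real = Re(z) * (1 + rnorm(20, sd = 0.01)),
      imaginary = Im(z) * (1 + rnorm(20, sd = 0.01))
    )
  })
  fit <- fit_rrc(impedance_spectrum(f, impedance = z_noisy))
  expect_equal(fit$circuit$rs_ohm, 500, tolerance = 0.05)
  expect_equal(fit$circuit$rp_ohm, 1e4, tolerance = 0.05)
  expect_equal(fit$circuit$cp_f, 150e-9, tolerance = 0.05)
})

test_that("the >100 Hz floor drops low-frequency points without changing the fit", {
  truth <- rrc_circuit(600, 8e3, 200e-9)
  f_hi <- 10^seq(log10(101), 3, length.out = 15)
  f_all <- c(10, 20, 50, 100, f_hi) # 100 Hz itself is excluded (strict >)
  fit_all <- fit_rrc(spectrum_from_circuit(truth, f_all))
  fit_hi <- fit_rrc(spectrum_from_circuit(truth, f_hi))
  expect_equal(fit_all$circuit$rs_ohm, fit_hi$circuit$rs_ohm)
  expect_equal(fit_all$circuit$rp_ohm, fit_hi$circuit$rp_ohm)
  expect_equal(fit_all$circuit$cp_f, fit_hi$circuit$cp_f)
  expect_equal(fit_all$n_points_used, 15L)
  expect_error(
    fit_rrc(spectrum_from_circuit(truth, c(10, 50, 101, 200))),
    "at least 3",
    class = "ectfield_error"
  )
})

test_that("spectrum CSV IO round-trips, sorts, and validates", {
  spec <- spectrum_from_circuit(
    rrc_circuit(500, 1e4, 150e-9),
    frequency_hz = c(300, 100, 1000)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  save_spectrum(spec, path)
  back <- load_spectrum(path)
  expect_equal(back$frequency_hz, sort(spec$frequency_hz))
  expect_equal(
    back[order(back$frequency_hz), ],
    spec[order(spec$frequency_hz), ],
    ignore_attr = TRUE
  )
  # missing column is named
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(frequency_hz = 1:3, z_real_ohm = 4:6), bad)
  expect_error(load_spectrum(bad), "z_imag_ohm", class = "ectfield_error")
})

test_that("tidiers expose circuit fits as tibbles", {
  fit <- fit_rrc(spectrum_from_circuit(rrc_circuit(500, 1e4, 150e-9)))
  td <- tidy(fit)
  expect_equal(td$term, c("rs_ohm", "rp_ohm", "cp_f"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$z1k_ohm, magnitude_at_1khz(fit$circuit))
  expect_s3_class(autoplot(fit), "ggplot")
})
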