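#' Reference R-RC circuit fits for ten measured subjects
#'
#' Equivalent-circuit parameters (Rs, Rp, Cp) fitted to bifrontal
#' ECT-electrode impedance spectra measured at low current in ten healthy
#' subjects (>100 Hz data only), together with the 1 kHz impedance
#' reported for each fitted circuit and the device-reported static
#' impedance averages. Useful as realistic inputs for [circuit_impedance()]
#' and [magnitude_at_1khz()] and for checking a fitting pipeline
#' end-to-end.
#'
#' For subject 207 the reported 1 kHz value (810 ohm) is inconsistent with
#' direct evaluation of the reported circuit (704 ohm), most likely a
#' transcription slip in the original record; the row is retained but the
#' `z1k_consistent` flag marks it.
#'
#' @return A tibble with columns `subject_id`, `thymatron_avg_ohm`
#'   (device-reported static impedance, session average), `rs_ohm`,
#'   `rp_ohm`, `cp_f`, `z1k_reported_ohm` and `z1k_consistent`.
#' @examples
#' fits <- eis_subject_fits()
#' magnitude_at_1khz(rrc_circuit(fits$rs_ohm[1], fits$rp_ohm[1], fits$cp_f[1]))
#' @export
eis_subject_fits <- function() {
  tibble(
    subject_id = as.character(201:210),
    thymatron_avg_ohm = c(
      1250, 1665, 1070, 1490, 1690, 1090, 810, 1389, 939, 885
    ),
    rs_ohm = c(522, 681, 506, 508, 555, 449, 372, 557, 432, 374),
    rp_ohm = 1e3 * c(
      9.89, 13.17, 5.52, 13.44, 22.59, 4.24, 2.84, 6.70, 2.57, 3.97
    ),
    cp_f = 1e-9 * c(175, 138, 210, 138, 119, 219, 294, 160, 263, 277),
    z1k_reported_ohm = c(
      1086, 1386, 960, 1297, 1475, 906, 810, 1203, 806, 723
    ),
    z1k_consistent = subject_id != "207"
  )
}

#' Calibrated scalp parameters for four clinical ECT subjects
#'
#' Subject-specific (deep-scalp conductivity, maximum superficial-scalp
#' conductivity) pairs obtained by calibrating MRI-derived adaptive head
#' models against each subject's clinical static and dynamic impedance,
#' with the saturation field implied by each maximum (see
#' [saturation_field()]). The association of the two middle parameter sets
#' with subject identifiers is ambiguous in the source records (one
#' identifier appears twice), so analyses should key on the parameter
#' values, not the ids.
#'
#' @return A tibble with columns `subject_id`, `sigma_ds_s_m`,
#'   `sigma_ss_max_s_m` and `saturation_field_v_m` (as reported, integer
#'   V/m).
#' @examples
#' adaptive_subject_params()
#' @export
adaptive_subject_params <- function() {
  tibble(
    subject_id = c("21908", "22035", "22035*", "21778"),
    sigma_ds_s_m = c(0.002, 4.5e-4, 0.008, 0.0012),
    sigma_ss_max_s_m = c(0.16, 0.5, 0.3, 0.4),
    saturation_field_v_m = c(428, 1185, 740, 963)
  )
}
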