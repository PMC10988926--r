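# broom-style accessors: tidy() flattens a result to a tibble of records,
# glance() gives a one-row summary.

#' @export
tidy.rrc_fit <- function(x, ...) {
  tibble(
    term = c("rs_ohm", "rp_ohm", "cp_f"),
    estimate = c(x$circuit$rs_ohm, x$circuit$rp_ohm, x$circuit$cp_f)
  )
}

#' @export
glance.rrc_fit <- function(x, ...) {
  tibble(
    rs_ohm = x$circuit$rs_ohm,
    rp_ohm = x$circuit$rp_ohm,
    cp_f = x$circuit$cp_f,
    z1k_ohm = x$z1k_ohm,
    residual_norm = x$residual_norm,
    n_points_used = x$n_points_used,
    frequency_floor_hz = x$frequency_floor_hz
  )
}

#' @export
tidy.fem_solution <- function(x, ...) {
  elems <- x$mesh$elems
  centers <- (x$mesh$nodes[elems[, 1], , drop = FALSE] +
    x$mesh$nodes[elems[, 2], , drop = FALSE] +
    x$mesh$nodes[elems[, 3], , drop = FALSE] +
    x$mesh$nodes[elems[, 4], , drop = FALSE] +
    x$mesh$nodes[elems[, 5], , drop = FALSE] +
    x$mesh$nodes[elems[, 6], , drop = FALSE] +
    x$mesh$nodes[elems[, 7], , drop = FALSE] +
    x$mesh$nodes[elems[, 8], , drop = FALSE]) / 8
  tibble(
    element = seq_len(nrow(elems)),
    x_m = centers[, 1], y_m = centers[, 2], z_m = centers[, 3],
    tissue = x$mesh$tissue,
    field_v_m = x$fields,
    sigma_s_m = x$conductivities
  )
}

#' @export
glance.fem_solution <- function(x, ...) {
  tibble(
    impedance_ohm = x$impedance_ohm,
    applied_current_a = x$bc$applied_current_a,
    n_nodes = length(x$potentials),
    n_elements = length(x$fields),
    peak_field_v_m = max(x$fields)
  )
}

#' @export
glance.adaptive_solution <- function(x, ...) {
  dplyr::mutate(
    glance.fem_solution(x),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @export
tidy.ect_calibration <- function(x, ...) {
  tibble(
    term = c("sigma_ds_s_m", "sigma_ss_max_s_m", "saturation_field_v_m"),
    estimate = c(
      x$scalp$deep_scalp_conductivity,
      x$scalp$max_superficial_conductivity,
      x$scalp$saturation_field
    )
  )
}

#' @export
glance.ect_calibration <- function(x, ...) {
  tibble(
    sigma_ds_s_m = x$scalp$deep_scalp_conductivity,
    sigma_ss_max_s_m = x$scalp$max_superficial_conductivity,
    static_ohm = x$static_ohm,
    dynamic_ohm = x$dynamic_ohm,
    static_rel_error = x$static_rel_error,
    dynamic_rel_error = x$dynamic_rel_error,
    evaluations = x$evaluations,
    converged = x$converged
  )
}
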