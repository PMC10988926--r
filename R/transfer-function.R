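#' Field-to-conductivity transfer function constants
#'
#' Population-level constants of the piecewise-linear transfer function
#' that maps local superficial-scalp electric-field magnitude to scalp
#' conductivity (see [sigma_ss()]). Defaults are the calibrated values for
#' 1 kHz representative-frequency modeling:
#' floor 5e-3 S/m, threshold 85 V/m, slope 4.49e-4 (S/m per V/m), offset
#' 0.032 S/m.
#'
#' @param floor_conductivity Conductivity (S/m) below the field threshold.
#' @param field_threshold Field magnitude (V/m) at which conductivity
#'   starts rising.
#' @param slope Rise rate (S/m per V/m) of the linear branch.
#' @param offset Intercept offset (S/m) of the linear branch, which
#'   evaluates as `slope * field - offset`.
#' @return An object of class `transfer_function_params`.
#' @export
transfer_function_params <- function(floor_conductivity = 5e-3,
                                     field_threshold = 85,
                                     slope = 4.49e-4,
                                     offset = 0.032) {
  check_scalar_positive(floor_conductivity, "floor_conductivity")
  check_scalar_positive(field_threshold, "field_threshold")
  check_scalar_positive(slope, "slope")
  check_scalar_positive(offset, "offset")
  if (slope * field_threshold - offset <= 0) {
    stop_invalid(
      "The linear branch must be positive at the threshold: require slope * field_threshold - offset > 0."
    )
  }
  structure(
    list(
      floor_conductivity = floor_conductivity,
      field_threshold = field_threshold,
      slope = slope, offset = offset
    ),
    class = "transfer_function_params"
  )
}

#' Saturation field for a given maximum scalp conductivity
#'
#' The linear branch `slope * field - offset` reaches the subject's maximum
#' superficial-scalp conductivity at the saturation field
#' `(max_conductivity + offset) / slope`; beyond it conductivity is
#' clamped. E.g. a 0.16 S/m maximum saturates near 428 V/m and a 0.5 S/m
#' maximum near 1185 V/m under the default constants.
#'
#' @param params A [transfer_function_params()].
#' @param max_conductivity Subject-specific maximum superficial-scalp
#'   conductivity (S/m); must exceed the branch value at the threshold,
#'   `slope * field_threshold - offset`, or no saturation knee exists.
#' @return Saturation field magnitude (V/m).
#' @examples
#' saturation_field(transfer_function_params(), 0.16) # ~427.6
#' @export
saturation_field <- function(params, max_conductivity) {
  if (!inherits(params, "transfer_function_params")) {
    stop_invalid("`params` must be created with transfer_function_params().")
  }
  check_scalar_positive(max_conductivity, "max_conductivity")
  knee_floor <- params$slope * params$field_threshold - params$offset
  if (max_conductivity <= knee_floor) {
    stop_invalid(sprintf(
      "`max_conductivity` (%g S/m) must exceed the branch value at the threshold (%g S/m), otherwise the saturation knee does not exist.",
      max_conductivity, knee_floor
    ))
  }
  (max_conductivity + params$offset) / params$slope
}

#' Subject-specific scalp conductivity parameters
#'
#' Two parameters are individualized per subject: the fixed deep-scalp
#' conductivity `deep_scalp_conductivity` and the maximum
#' superficial-scalp conductivity `max_superficial_conductivity`; the
#' saturation field follows from the latter via [saturation_field()].
#' Deep-scalp values in calibrated subjects fall between 4.5e-4 and
#' 0.008 S/m; those bounds are configurable soft defaults, not physical
#' limits.
#'
#' @param deep_scalp_conductivity Deep-scalp conductivity (S/m).
#' @param max_superficial_conductivity Saturated superficial-scalp
#'   conductivity (S/m); must exceed the transfer-function floor.
#' @param tf A [transfer_function_params()].
#' @param deep_scalp_bounds Length-2 admissible range for
#'   `deep_scalp_conductivity` (S/m).
#' @return An object of class `scalp_params` with the derived
#'   `saturation_field` element (V/m).
#' @examples
#' scalp_params(0.002, 0.16) # saturation at ~428 V/m
#' @export
scalp_params <- function(deep_scalp_conductivity,
                         max_superficial_conductivity,
                         tf = transfer_function_params(),
                         deep_scalp_bounds = c(4.5e-4, 0.008)) {
  check_scalar_positive(deep_scalp_conductivity, "deep_scalp_conductivity")
  check_scalar_positive(
    max_superficial_conductivity,
    "max_superficial_conductivity"
  )
  if (deep_scalp_conductivity < deep_scalp_bounds[1] ||
    deep_scalp_conductivity > deep_scalp_bounds[2]) {
    stop_invalid(sprintf(
      "`deep_scalp_conductivity` (%g S/m) is outside the admissible range [%g, %g] S/m.",
      deep_scalp_conductivity, deep_scalp_bounds[1], deep_scalp_bounds[2]
    ))
  }
  if (max_superficial_conductivity <= tf$floor_conductivity) {
    stop_invalid(
      "`max_superficial_conductivity` must exceed the transfer-function floor conductivity."
    )
  }
  knee_floor <- tf$slope * tf$field_threshold - tf$offset
  # a maximum at or below the branch value at the threshold (degenerate,
  # near-flat transfer function) clamps from the threshold onwards
  e_sat <- if (max_superficial_conductivity > knee_floor) {
    saturation_field(tf, max_superficial_conductivity)
  } else {
    tf$field_threshold
  }
  structure(
    list(
      deep_scalp_conductivity = deep_scalp_conductivity,
      max_superficial_conductivity = max_superficial_conductivity,
      saturation_field = e_sat,
      tf = tf
    ),
    class = "scalp_params"
  )
}

#' @export
print.scalp_params <- function(x, ...) {
  cat(sprintf(
    "<scalp_params> deep scalp %g S/m; superficial max %g S/m (saturates at %.0f V/m)\n",
    x$deep_scalp_conductivity, x$max_superficial_conductivity,
    x$saturation_field
  ))
  invisible(x)
}

#' Superficial-scalp conductivity as a function of local field
#'
#' The adaptive-conductivity transfer function: conductivity stays at the
#' floor below the field threshold, rises linearly as
#' `slope * field - offset` between the threshold and the subject's
#' saturation field, and is clamped at the subject maximum beyond it.
#' The function is evaluated on the Euclidean magnitude of the local
#' (element-averaged) electric-field vector.
#'
#' The printed constants leave a small upward jump at the threshold (floor
#' 0.005 vs branch value 0.0061650 S/m there); it is reproduced verbatim.
#' For solver robustness an optional linear blend of width `blend_width`
#' V/m around the threshold can bridge the jump; it defaults to 0 (off).
#'
#' @param field Electric-field magnitude(s) (V/m), >= 0 (vectorized).
#' @param params A [transfer_function_params()].
#' @param scalp A [scalp_params()].
#' @param blend_width Optional smoothing width (V/m) centered on the
#'   threshold; 0 disables smoothing.
#' @return Conductivity (S/m), same length as `field`.
#' @examples
#' tf <- transfer_function_params()
#' sp <- scalp_params(0.002, 0.16)
#' sigma_ss(c(50, 200, 2000), tf, sp)
#' @export
sigma_ss <- function(field, params, scalp, blend_width = 0) {
  if (!inherits(params, "transfer_function_params")) {
    stop_invalid("`params` must be created with transfer_function_params().")
  }
  if (!inherits(scalp, "scalp_params")) {
    stop_invalid("`scalp` must be created with scalp_params().")
  }
  if (!is.numeric(field) || any(!is.finite(field)) || any(field < 0)) {
    stop_invalid("`field` must be finite and non-negative (a magnitude).")
  }
  e_sat <- scalp$saturation_field
  s_max <- scalp$max_superficial_conductivity
  b <- params$field_threshold
  out <- ifelse(
    field < b,
    params$floor_conductivity,
    pmin(params$slope * field - params$offset, s_max)
  )
  out[field >= e_sat] <- s_max
  if (blend_width > 0) {
    lo <- b - blend_width / 2
    hi <- b + blend_width / 2
    in_blend <- field >= lo & field < hi
    if (any(in_blend)) {
      v_lo <- params$floor_conductivity
      v_hi <- pmin(params$slope * hi - params$offset, s_max)
      w <- (field[in_blend] - lo) / (hi - lo)
      out[in_blend] <- (1 - w) * v_lo + w * v_hi
    }
  }
  # the subject maximum can sit below the floor only in degenerate configs;
  # clamp so the stated bounds always hold
  pmin(pmax(out, min(params$floor_conductivity, s_max)), s_max)
}

#' Fixed tissue conductivities
#'
#' The non-adaptive compartments carry fixed, subject-independent isotropic
#' conductivities, taken at the 1 kHz representative frequency: skull 0.01,
#' gray matter 0.276, white matter 0.126, CSF/meninges 0.85, air 1e-15 and
#' electrode gel 0.018 S/m. Deep scalp ("deep_scalp") and superficial
#' scalp ("superficial_scalp") carry `NA` here: the former is set per
#' subject via [scalp_params()], the latter adapts to the local field.
#'
#' @param ... Named overrides or additions, e.g. `skull = 0.012`.
#' @return A tibble with columns `tissue` and `sigma_s_m`.
#' @examples
#' tissue_table()
#' tissue_table(skull = 0.015)
#' @export
tissue_table <- function(...) {
  base <- c(
    superficial_scalp = NA_real_,
    deep_scalp = NA_real_,
    skull = 0.01,
    csf = 0.85,
    gray_matter = 0.276,
    white_matter = 0.126,
    air = 1e-15,
    gel = 0.018
  )
  overrides <- c(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop_invalid("Tissue overrides must be named, e.g. skull = 0.012.")
    }
    bad <- overrides[!is.na(overrides) & overrides <= 0]
    if (length(bad)) {
      stop_invalid(sprintf(
        "Tissue conductivities must be positive; got %s.",
        paste(sprintf("%s = %g", names(bad), bad), collapse = ", ")
      ))
    }
    base[names(overrides)] <- overrides
  }
  tibble(tissue = names(base), sigma_s_m = unname(base))
}

#' Read / write a model configuration
#'
#' JSON or YAML (by extension) with blocks `transfer_function`
#' (floor_conductivity, field_threshold, slope, offset), `tissues`
#' (label: conductivity) and `subject` (deep_scalp_conductivity,
#' max_superficial_conductivity). Absent blocks fall back to package
#' defaults.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A list with elements `tf` ([transfer_function_params()]),
#'   `tissues` (tibble) and `scalp` ([scalp_params()] or NULL).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("No such file: %s", path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_invalid(sprintf("Unsupported config extension '.%s' (use .json/.yaml).", ext))
  )
  tf <- do.call(transfer_function_params, as.list(cfg$transfer_function %||% list()))
  tissues <- do.call(tissue_table, as.list(cfg$tissues %||% list()))
  scalp <- NULL
  if (!is.null(cfg$subject)) {
    scalp <- scalp_params(
      deep_scalp_conductivity = cfg$subject$deep_scalp_conductivity,
      max_superficial_conductivity = cfg$subject$max_superficial_conductivity,
      tf = tf
    )
  }
  list(tf = tf, tissues = tissues, scalp = scalp)
}

#' @rdname load_model_config
#' @param tf A [transfer_function_params()].
#' @param tissues A [tissue_table()] tibble.
#' @param scalp Optional [scalp_params()].
#' @export
save_model_config <- function(path, tf = transfer_function_params(),
                              tissues = tissue_table(), scalp = NULL) {
  fixed <- tissues[!is.na(tissues$sigma_s_m), ]
  cfg <- list(
    transfer_function = tf[c(
      "floor_conductivity", "field_threshold", "slope", "offset"
    )],
    tissues = as.list(setNames(fixed$sigma_s_m, fixed$tissue))
  )
  if (!is.null(scalp)) {
    cfg$subject <- list(
      deep_scalp_conductivity = scalp$deep_scalp_conductivity,
      max_superficial_conductivity = scalp$max_superficial_conductivity
    )
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(cfg, path),
    stop_invalid(sprintf("Unsupported config extension '.%s' (use .json/.yaml).", ext))
  )
  invisible(path)
}
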