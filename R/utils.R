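# Internal validation helpers. All user-facing validation errors carry the
# class "ectfield_error" so tests can target them precisely.

stop_invalid <- function(msg, ..., class = character()) {
  abort(msg, class = c(class, "ectfield_error"), ...)
}

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
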