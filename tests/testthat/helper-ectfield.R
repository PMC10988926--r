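# Shared fixtures: everything is generated in code at test time.

default_pulse_spec <- function(duration = 1, sample_rate = 1e5) {
  pulse_train_spec(
    amplitude = 0.9, pulse_width = 5e-4, period = 0.05,
    duration = duration, sample_rate = sample_rate
  )
}

# coarse bifrontal slab for quick FEM tests
coarse_phantom <- function(inplane = 0.02) {
  build_phantom(phantom_spec(inplane_size_m = inplane))
}

# the package's default phantom (used where the resolution matters)
default_phantom_cached <- local({
  mesh <- NULL
  function() {
    if (is.null(mesh)) mesh <<- build_phantom(phantom_spec())
    mesh
  }
})

cg_settings <- function(tol = 1e-3, ...) {
  solver_settings(linear_tol = tol, linear_solver = "cg", ...)
}

tight_settings <- function(...) {
  solver_settings(linear_tol = 1e-10, linear_solver = "cg", ...)
}

# six-layer stack reused by oracle tests
six_layer_stack <- function() {
  tibble::tibble(
    tissue = c(
      "superficial_scalp", "deep_scalp", "skull", "csf",
      "gray_matter", "white_matter"
    ),
    thickness_m = c(0.0035, 0.0035, 0.007, 0.003, 0.004, 0.006)
  )
}

fixed_sigma_map <- function(sigma_ds = 0.002, sigma_ss = 0.005) {
  c(
    superficial_scalp = sigma_ss, deep_scalp = sigma_ds, skull = 0.01,
    csf = 0.85, gray_matter = 0.276, white_matter = 0.126, gel = 0.018,
    air = 1e-15
  )
}
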