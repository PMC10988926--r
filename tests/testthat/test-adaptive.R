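test_that("at 2 uA the adaptive solve reduces to the floor-conductivity linear solve", {
  mesh <- coarse_phantom()
  scalp <- scalp_params(0.002, 0.16)
  sol <- solve_adaptive(
    mesh,
    scalp = scalp, bc = boundary_condition(2e-6), settings = cg_settings()
  )
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2)
  # fields in the scalp stay far below the 85 V/m threshold
  ss <- mesh$tissue == "superficial_scalp"
  expect_lt(max(sol$fields[ss]), 1)
  expect_true(all(sol$conductivities[ss] == 5e-3))
  lin <- solve_linear(
    mesh, sol$conductivities, boundary_condition(2e-6), cg_settings()
  )
  expect_equal(sol$impedance_ohm, lin$impedance_ohm, tolerance = 1e-6)
})

test_that("dynamic impedance falls below static impedance", {
  mesh <- coarse_phantom()
  scalp <- scalp_params(0.002, 0.16)
  z_static <- solve_adaptive(
    mesh,
    scalp = scalp, bc = boundary_condition(2e-6), settings = cg_settings()
  )$impedance_ohm
  dyn <- solve_adaptive(
    mesh,
    scalp = scalp, bc = boundary_condition(0.9), settings = cg_settings()
  )
  expect_true(dyn$converged)
  expect_lt(dyn$impedance_ohm, z_static)
  # the scalp under the electrodes actually saturated
  ss <- mesh$tissue == "superficial_scalp"
  expect_gt(max(dyn$conductivities[ss]), 0.15)
})

test_that("the converged state is a fixed point of the transfer function", {
  mesh <- coarse_phantom()
  tf <- transfer_function_params()
  scalp <- scalp_params(0.002, 0.16)
  sol <- solve_adaptive(
    mesh,
    scalp = scalp, tf = tf, bc = boundary_condition(0.9),
    settings = cg_settings()
  )
  expect_true(sol$converged)
  ss <- which(mesh$tissue == "superficial_scalp")
  reevaluated <- sigma_ss(sol$fields[ss], tf, scalp)
  expect_lt(
    max(abs(reevaluated - sol$conductivities[ss]) / sol$conductivities[ss]),
    5e-3
  )
})

test_that("a flat transfer function removes the intensity dependence", {
  mesh <- coarse_phantom()
  # degenerate subject: saturation equal to the floor
  tf <- transfer_function_params()
  scalp <- scalp_params(0.002, 5e-3 + 1e-9)
  s <- cg_settings(tol = 1e-8)
  z_static <- solve_adaptive(
    mesh,
    scalp = scalp, tf = tf, bc = boundary_condition(2e-6), settings = s
  )$impedance_ohm
  z_dynamic <- solve_adaptive(
    mesh,
    scalp = scalp, tf = tf, bc = boundary_condition(0.9), settings = s
  )$impedance_ohm
  expect_equal(z_dynamic, z_static, tolerance = 1e-4)
})

test_that("terminal impedance is non-increasing in applied current", {
  mesh <- default_phantom_cached()
  scalp <- scalp_params(0.002, 0.16)
  z <- vapply(
    c(2e-6, 1e-3, 0.1, 0.9),
    function(i) {
      solve_adaptive(
        mesh,
        scalp = scalp, bc = boundary_condition(i), settings = cg_settings()
      )$impedance_ohm
    },
    numeric(1)
  )
  expect_true(all(diff(z) <= 1e-6 * z[-length(z)]))
  # 1 mA already shows a lower impedance than the 2 uA test current
  expect_lt(z[2], z[1])
})

test_that("the Picard loop matches a brute-force fixed point on a tiny mesh", {
  mesh <- build_phantom(phantom_spec(inplane_size_m = 0.03))
  tf <- transfer_function_params()
  scalp <- scalp_params(0.002, 0.16)
  tissues <- tissue_table()
  bc <- boundary_condition(0.9)
  s <- cg_settings(tol = 1e-8, adaptive_tol = 1e-6)

  # independent brute force: plain substitution iteration built only from
  # solve_linear and sigma_ss, no relaxation
  sig_map <- fixed_sigma_map(sigma_ds = 0.002, sigma_ss = tf$floor_conductivity)
  sigma <- unname(sig_map[mesh$tissue])
  ss <- mesh$tissue == "superficial_scalp"
  z_brute <- NA_real_
  for (i in 1:200) {
    sol <- solve_linear(mesh, sigma, bc, s)
    sigma_new <- sigma
    sigma_new[ss] <- sigma_ss(sol$fields[ss], tf, scalp)
    if (max(abs(sigma_new - sigma) / sigma) < 1e-6 &&
      !is.na(z_brute) &&
      abs(sol$impedance_ohm - z_brute) / z_brute < 1e-6) {
      break
    }
    z_brute <- sol$impedance_ohm
    sigma <- sigma_new
  }

  adaptive <- solve_adaptive(
    mesh,
    tissues = tissues, scalp = scalp, tf = tf, bc = bc, settings = s
  )
  expect_true(adaptive$converged)
  expect_equal(adaptive$impedance_ohm, sol$impedance_ohm, tolerance = 1e-4)
  expect_equal(
    adaptive$conductivities[ss], sigma[ss],
    tolerance = 1e-3
  )
})

test_that("the iteration cap flags non-convergence instead of erroring", {
  mesh <- build_phantom(phantom_spec(inplane_size_m = 0.03))
  sol <- solve_adaptive(
    mesh,
    scalp = scalp_params(0.002, 0.16), bc = boundary_condition(0.9),
    settings = cg_settings(max_iterations = 2)
  )
  expect_false(sol$converged)
  expect_equal(sol$iterations, 2L)
  expect_equal(nrow(sol$trace), 2L)
  expect_true(all(c("impedance_ohm", "max_sigma_rel_change") %in% names(sol$trace)))
})

test_that("solve results export to JSON + CSV", {
  mesh <- build_phantom(phantom_spec(inplane_size_m = 0.03))
  sol <- solve_adaptive(
    mesh,
    scalp = scalp_params(0.002, 0.16), bc = boundary_condition(2e-6),
    settings = cg_settings()
  )
  path <- withr::local_tempfile(fileext = ".json")
  save_solution(sol, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$impedance_ohm, sol$impedance_ohm)
  csv <- readr::read_csv(
    paste0(tools::file_path_sans_ext(path), "_elements.csv"),
    show_col_types = FALSE
  )
  expect_equal(nrow(csv), nrow(mesh$elems))
})
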