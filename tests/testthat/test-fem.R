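test_that("a uniform column reproduces the analytic resistance", {
  mesh <- column_phantom(
    tibble::tibble(tissue = "skull", thickness_m = 0.01),
    cross_section_m = c(0.01, 0.01),
    element_size_m = 0.002, inplane_size_m = 0.005
  )
  sol <- solve_linear(
    mesh, rep(0.01, nrow(mesh$elems)), boundary_condition(1e-3),
    tight_settings()
  )
  # R = L / (sigma * A) = 0.01 / (0.01 * 1e-4) = 1e4 ohm; uniform vertical
  # flow is in the trilinear space, so the match is exact
  expect_equal(sol$impedance_ohm, 1e4, tolerance = 1e-9)
})

test_that("a six-layer stack matches the series-resistance sum within 1%", {
  layers <- six_layer_stack()
  mesh <- column_phantom(layers,
    cross_section_m = c(0.02, 0.02),
    element_size_m = 0.00125, inplane_size_m = 0.01
  )
  sig_map <- fixed_sigma_map()
  sigma <- unname(sig_map[mesh$tissue])
  sol <- solve_linear(mesh, sigma, boundary_condition(2e-6), tight_settings())
  oracle <- sum(layers$thickness_m / (sig_map[layers$tissue] * 4e-4))
  expect_equal(sol$impedance_ohm, oracle, tolerance = 0.01)
})

test_that("the solution scales linearly in conductivity and current", {
  mesh <- coarse_phantom()
  sigma <- unname(fixed_sigma_map()[mesh$tissue])
  s <- tight_settings()
  base <- solve_linear(mesh, sigma, boundary_condition(1e-3), s)
  doubled <- solve_linear(mesh, 2 * sigma, boundary_condition(1e-3), s)
  expect_equal(doubled$impedance_ohm, base$impedance_ohm / 2, tolerance = 1e-8)
  more_current <- solve_linear(mesh, sigma, boundary_condition(2e-3), s)
  expect_equal(more_current$impedance_ohm, base$impedance_ohm, tolerance = 1e-8)
  expect_equal(more_current$potentials, 2 * base$potentials, tolerance = 1e-7)
})

test_that("sparse CG agrees with a dense solve on a small mesh", {
  mesh <- column_phantom(
    tibble::tibble(
      tissue = c("superficial_scalp", "skull"), thickness_m = c(0.004, 0.006)
    ),
    cross_section_m = c(0.008, 0.008),
    element_size_m = 0.002, inplane_size_m = 0.002
  )
  expect_lte(nrow(mesh$elems), 1000)
  sigma <- unname(fixed_sigma_map()[mesh$tissue])
  bc <- boundary_condition(1e-3)
  sol_cg <- solve_linear(mesh, sigma, bc, tight_settings())

  # dense path: same assembled operator, solved by base R dense elimination
  op <- getFromNamespace("fem_operator", "ectfield")(mesh)
  K <- getFromNamespace("assemble_stiffness", "ectfield")(
    op, mesh$elems, pmax(sigma, 1e-15)
  )
  f <- getFromNamespace("load_vector", "ectfield")(
    mesh, list(
      driven_faces = mesh$driven_faces, driven_areas = mesh$driven_areas
    ),
    bc$applied_current_a
  )
  ground <- unique(as.vector(mesh$ground_faces))
  free <- setdiff(seq_len(nrow(mesh$nodes)), ground)
  v_dense <- numeric(nrow(mesh$nodes))
  v_dense[free] <- solve(as.matrix(K[free, free]), f[free])
  expect_lt(max(abs(v_dense - sol_cg$potentials)) / max(abs(v_dense)), 1e-10)

  # and with the packaged direct solver
  sol_dir <- solve_linear(
    mesh, sigma, bc, solver_settings(linear_solver = "direct")
  )
  expect_lt(
    max(abs(v_dense - sol_dir$potentials)) / max(abs(v_dense)), 1e-10
  )
})

test_that("discrete current is conserved across cut planes", {
  mesh <- coarse_phantom()
  sigma <- unname(fixed_sigma_map()[mesh$tissue])
  sol <- solve_linear(mesh, sigma, boundary_condition(1e-3), tight_settings())
  # a vertical plane between the electrodes carries the full current
  lx <- mesh$spec$extent_m[1]
  i_cut <- cut_plane_current(sol, lx / 2, axis = 1)
  expect_equal(abs(i_cut), 1e-3, tolerance = 1e-3)
  # a horizontal plane below both electrodes carries zero net current
  i_horiz <- cut_plane_current(sol, 0.01, axis = 3)
  expect_lt(abs(i_horiz), 1e-3 * 1e-3)
})

test_that("swapping driven and ground terminals leaves impedance unchanged", {
  mesh <- coarse_phantom()
  sigma <- unname(fixed_sigma_map()[mesh$tissue])
  s <- tight_settings()
  z1 <- solve_linear(mesh, sigma, boundary_condition(1e-3), s)$impedance_ohm
  z2 <- solve_linear(
    mesh, sigma, boundary_condition(1e-3, swap_terminals = TRUE), s
  )$impedance_ohm
  expect_equal(z2, z1, tolerance = 1e-6)
})

test_that("invalid conductivity vectors and disconnected systems error", {
  mesh <- coarse_phantom()
  expect_error(
    solve_linear(mesh, rep(0.1, 3), boundary_condition(1e-3)),
    "per element",
    class = "ectfield_error"
  )
  bad <- rep(0.1, nrow(mesh$elems))
  bad[1] <- -1
  expect_error(
    solve_linear(mesh, bad, boundary_condition(1e-3)),
    "positive",
    class = "ectfield_error"
  )
})

test_that("solution tidiers report per-element records and summaries", {
  mesh <- coarse_phantom()
  sigma <- unname(fixed_sigma_map()[mesh$tissue])
  sol <- solve_linear(mesh, sigma, boundary_condition(1e-3), cg_settings())
  td <- tidy(sol)
  expect_equal(nrow(td), nrow(mesh$elems))
  expect_true(all(c("tissue", "field_v_m", "sigma_s_m") %in% names(td)))
  gl <- glance(sol)
  expect_equal(gl$impedance_ohm, sol$impedance_ohm)
})
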