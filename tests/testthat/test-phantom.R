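test_that("slab phantom partitions its grid into labeled hexahedra", {
  spec <- phantom_spec(inplane_size_m = 0.02)
  mesh <- build_phantom(spec)
  g <- mesh$grid
  n_cols <- (length(g$x) - 1) * (length(g$y) - 1)
  n_base <- n_cols * (g$n_base_levels - 1)
  n_gel <- sum(mesh$tissue == "gel")
  expect_equal(nrow(mesh$elems), n_base + n_gel)
  expect_setequal(
    unique(mesh$tissue),
    c(
      "superficial_scalp", "deep_scalp", "skull", "csf",
      "gray_matter", "white_matter", "gel"
    )
  )
  # terminal sets non-empty and disjoint
  expect_gt(nrow(mesh$driven_faces), 0)
  expect_gt(nrow(mesh$ground_faces), 0)
  expect_length(
    intersect(as.vector(mesh$driven_faces), as.vector(mesh$ground_faces)), 0
  )
})

test_that("mirror-symmetric specs produce mirror-symmetric meshes", {
  mesh <- coarse_phantom()
  lx <- mesh$spec$extent_m[1]
  mirrored <- cbind(lx - mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3])
  key <- function(m) sort(apply(round(m, 12), 1, paste, collapse = "_"))
  expect_equal(key(mirrored), key(mesh$nodes))
  # swapping terminals mirrors the electrode footprint
  expect_equal(
    sort(round(lx - mesh$nodes[mesh$driven_faces, 1], 12)),
    sort(round(mesh$nodes[mesh$ground_faces, 1], 12))
  )
})

test_that("spec validation rejects unresolved layers and bad electrodes", {
  expect_error(
    phantom_spec(element_size_m = 0.0021), # > csf thickness / 2
    "thinnest",
    class = "ectfield_error"
  )
  expect_error(
    phantom_spec(electrode_centers = rbind(c(0.03, 0.0375), c(0.05, 0.0375))),
    "overlap",
    class = "ectfield_error"
  )
  expect_error(
    phantom_spec(electrode_centers = rbind(c(0.01, 0.0375), c(0.12, 0.0375))),
    "off the phantom",
    class = "ectfield_error"
  )
})

test_that("tissue volumes match the analytic layer volumes", {
  spec <- phantom_spec()
  mesh <- build_phantom(spec)
  vols <- mesh_volumes(mesh)
  area <- prod(spec$extent_m)
  for (i in seq_len(nrow(spec$layers))) {
    expect_equal(
      vols$volume_m3[vols$tissue == spec$layers$tissue[i]],
      area * spec$layers$thickness_m[i],
      tolerance = 0.005
    )
  }
  expect_equal(
    vols$volume_m3[vols$tissue == "gel"],
    2 * prod(spec$electrode_size) * spec$gel_thickness_m,
    tolerance = 0.005
  )
})

test_that("halving the element size leaves uniform-phantom impedance stable", {
  sig <- 0.1
  z_of <- function(inplane, elem) {
    mesh <- build_phantom(
      phantom_spec(inplane_size_m = inplane, element_size_m = elem)
    )
    solve_linear(
      mesh, rep(sig, nrow(mesh$elems)), boundary_condition(1e-3),
      tight_settings()
    )$impedance_ohm
  }
  z1 <- z_of(0.007, 0.0015) # the default resolution
  z2 <- z_of(0.0035, 0.00075)
  expect_lt(abs(z2 - z1) / z1, 0.02)
})

test_that("shell phantom builds a closed multilayer ball with gel patches", {
  spec <- phantom_spec("concentric_shells", inplane_size_m = 0.018)
  mesh <- build_phantom(spec)
  expect_setequal(
    unique(mesh$tissue),
    c(
      "superficial_scalp", "deep_scalp", "skull", "csf",
      "gray_matter", "white_matter", "gel"
    )
  )
  # every non-gel node radius lies within the shell stack
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_gte(min(r), spec$inner_radius_m - 1e-9)
  expect_lte(max(r), spec$layers$outer_radius_m[1] + spec$gel_thickness_m + 1e-9)
  # terminal faces sit on the outer gel surface
  r_term <- sqrt(rowSums(mesh$nodes[mesh$driven_faces, ]^2))
  expect_equal(
    r_term, rep(spec$layers$outer_radius_m[1] + spec$gel_thickness_m,
      length(r_term)
    ),
    tolerance = 1e-9
  )
  # conductive component is connected: a solve succeeds
  sol <- solve_linear(
    mesh, rep(0.1, nrow(mesh$elems)), boundary_condition(1e-3),
    cg_settings()
  )
  expect_gt(sol$impedance_ohm, 0)
})

test_that("mesh VTK round trip preserves geometry, labels and terminals", {
  mesh <- coarse_phantom()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(mesh, path)
  back <- read_mesh(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-12)
  expect_identical(back$elems, mesh$elems)
  expect_identical(back$tissue, mesh$tissue)
  expect_identical(back$driven_faces, mesh$driven_faces)
  expect_identical(back$ground_faces, mesh$ground_faces)
})

test_that("reading meshes with unknown or missing labels fails loudly", {
  mesh <- coarse_phantom()
  path <- withr::local_tempfile(fileext = ".vtk")
  write_mesh(mesh, path)
  # corrupt the sidecar with a label that is not a known tissue
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  names(side$tissue_ids)[1] <- "plastic"
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_mesh(path), "plastic", class = "ectfield_error")

  # truncate the cell data: cells lack labels
  lines <- readLines(path)
  i <- grep("^LOOKUP_TABLE", lines)
  writeLines(head(lines, i + 10), path)
  jsonlite::write_json(
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  expect_error(read_mesh(path), "lack", class = "ectfield_error")
})
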