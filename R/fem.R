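# Quasi-static volume-conductor FEM: first-order (trilinear) hexahedral
# elements with element-constant conductivity, assembled with the Matrix
# package and solved either by Jacobi-preconditioned conjugate gradients or
# by sparse Cholesky. The governing equation is the current-conservation
# Laplace problem div(sigma grad V) = 0 with a uniform current density over
# the driven electrode face and V = 0 on the ground face.

# reference-corner signs in VTK hexahedron order
HEX_CORNERS <- matrix(
  c(
    -1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
    -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1
  ),
  ncol = 3, byrow = TRUE
)

# dN_i/dxi_a at a reference point, 8 x 3
shape_grad <- function(xi) {
  s <- HEX_CORNERS
  cbind(
    s[, 1] * (1 + xi[2] * s[, 2]) * (1 + xi[3] * s[, 3]),
    (1 + xi[1] * s[, 1]) * s[, 2] * (1 + xi[3] * s[, 3]),
    (1 + xi[1] * s[, 1]) * (1 + xi[2] * s[, 2]) * s[, 3]
  ) / 8
}

GAUSS_PTS <- HEX_CORNERS / sqrt(3)

# Per-element unit-conductivity stiffness (M x 64, row-major over the 8x8
# node pairs), element volumes, and the center gradient operator used for
# element fields. Vectorized across elements, one Gauss point at a time.
fem_operator <- function(mesh) {
  elems <- mesh$elems
  m <- nrow(elems)
  xs <- matrix(mesh$nodes[elems, 1], m, 8)
  ys <- matrix(mesh$nodes[elems, 2], m, 8)
  zs <- matrix(mesh$nodes[elems, 3], m, 8)

  ke <- matrix(0, m, 64)
  vol <- numeric(m)
  b_at <- function(xi) {
    g <- shape_grad(xi)
    j11 <- xs %*% g[, 1]; j12 <- ys %*% g[, 1]; j13 <- zs %*% g[, 1]
    j21 <- xs %*% g[, 2]; j22 <- ys %*% g[, 2]; j23 <- zs %*% g[, 2]
    j31 <- xs %*% g[, 3]; j32 <- ys %*% g[, 3]; j33 <- zs %*% g[, 3]
    det <- j11 * (j22 * j33 - j23 * j32) -
      j12 * (j21 * j33 - j23 * j31) +
      j13 * (j21 * j32 - j22 * j31)
    # inverse via adjugate; inv[a,b] = adj_ab / det
    i11 <- (j22 * j33 - j23 * j32) / det
    i12 <- (j13 * j32 - j12 * j33) / det
    i13 <- (j12 * j23 - j13 * j22) / det
    i21 <- (j23 * j31 - j21 * j33) / det
    i22 <- (j11 * j33 - j13 * j31) / det
    i23 <- (j13 * j21 - j11 * j23) / det
    i31 <- (j21 * j32 - j22 * j31) / det
    i32 <- (j12 * j31 - j11 * j32) / det
    i33 <- (j11 * j22 - j12 * j21) / det
    # grad_x N_i = Jinv %*% grad_xi N_i, per element
    bx <- by <- bz <- matrix(0, m, 8)
    for (i in 1:8) {
      bx[, i] <- i11 * g[i, 1] + i12 * g[i, 2] + i13 * g[i, 3]
      by[, i] <- i21 * g[i, 1] + i22 * g[i, 2] + i23 * g[i, 3]
      bz[, i] <- i31 * g[i, 1] + i32 * g[i, 2] + i33 * g[i, 3]
    }
    list(bx = bx, by = by, bz = bz, det = abs(as.numeric(det)))
  }

  for (gp in 1:8) {
    b <- b_at(GAUSS_PTS[gp, ])
    vol <- vol + b$det
    for (i in 1:8) {
      for (j in i:8) {
        kij <- b$det *
          (b$bx[, i] * b$bx[, j] + b$by[, i] * b$by[, j] +
            b$bz[, i] * b$bz[, j])
        ke[, (i - 1) * 8 + j] <- ke[, (i - 1) * 8 + j] + kij
        if (j > i) ke[, (j - 1) * 8 + i] <- ke[, (j - 1) * 8 + i] + kij
      }
    }
  }
  b0 <- b_at(c(0, 0, 0))
  list(
    ke = ke, vol = vol,
    b0x = b0$bx, b0y = b0$by, b0z = b0$bz,
    n_nodes = nrow(mesh$nodes)
  )
}

element_volumes <- function(mesh) {
  fem_operator(mesh)$vol
}

# sparse stiffness for a subset of elements (default all)
assemble_stiffness <- function(op, elems, sigma, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(elems))
  e <- elems[subset, , drop = FALSE]
  ke <- op$ke[subset, , drop = FALSE] * sigma
  ii <- jj <- matrix(0L, length(subset), 64)
  for (i in 1:8) {
    for (j in 1:8) {
      col <- (i - 1) * 8 + j
      ii[, col] <- e[, i]
      jj[, col] <- e[, j]
    }
  }
  Matrix::sparseMatrix(
    i = as.vector(ii), j = as.vector(jj), x = as.vector(ke),
    dims = c(op$n_nodes, op$n_nodes), repr = "C"
  )
}

# Jacobi-preconditioned conjugate gradients
pcg_solve <- function(K, b, x0 = NULL, tol = 1e-3, maxit = NULL) {
  n <- length(b)
  maxit <- maxit %||% max(2000L, 20L * ceiling(sqrt(n)))
  d <- Matrix::diag(K)
  if (any(d <= 0)) {
    stop_invalid("System matrix has non-positive diagonal entries (disconnected or invalid conductivities).")
  }
  x <- x0 %||% numeric(n)
  r <- b - as.numeric(K %*% x)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(list(x = numeric(n), iterations = 0L, rel_residual = 0))
  }
  z <- r / d
  p <- z
  rz <- sum(r * z)
  rel <- sqrt(sum(r^2)) / bnorm
  it <- 0L
  while (rel > tol && it < maxit) {
    it <- it + 1L
    kp <- as.numeric(K %*% p)
    alpha <- rz / sum(p * kp)
    if (!is.finite(alpha)) {
      stop_invalid("Conjugate gradients broke down (singular or indefinite system).")
    }
    x <- x + alpha * p
    r <- r - alpha * kp
    rel <- sqrt(sum(r^2)) / bnorm
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = it, rel_residual = rel)
}

#' Boundary conditions for a terminal-driven solve
#'
#' Total current `applied_current_a` is injected as a uniform current
#' density over the driven terminal faces; the ground terminal faces are
#' clamped to 0 V. The defaults model the two clinical conditions: 2e-6 A
#' (static impedance test) and 0.9 A (stimulus / dynamic impedance).
#'
#' @param applied_current_a Total injected current (A), > 0.
#' @param swap_terminals Drive the mesh's ground patch instead (and ground
#'   the driven patch); useful for symmetry checks.
#' @return An object of class `boundary_condition`.
#' @export
boundary_condition <- function(applied_current_a = 0.9,
                               swap_terminals = FALSE) {
  check_scalar_positive(applied_current_a, "applied_current_a")
  check_flag(swap_terminals, "swap_terminals")
  structure(
    list(
      applied_current_a = applied_current_a,
      swap_terminals = swap_terminals
    ),
    class = "boundary_condition"
  )
}

#' Solver settings
#'
#' @param linear_tol Relative residual tolerance of the linear solver
#'   (default 1e-3).
#' @param adaptive_tol Convergence tolerance of the adaptive loop: both the
#'   relative impedance change and the maximum relative conductivity change
#'   between successive iterations must fall below it (default 1e-3).
#' @param max_iterations Adaptive (Picard) iteration cap (default 1000).
#' @param relaxation Under-relaxation factor omega in (0, 1] applied to the
#'   conductivity update (default 0.5).
#' @param linear_solver `"cg"` (Jacobi-preconditioned conjugate gradients,
#'   default) or `"direct"` (sparse Cholesky).
#' @param blend_width Optional smoothing width (V/m) passed to
#'   [sigma_ss()] (default 0: the transfer function's threshold jump is
#'   kept as printed).
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(linear_tol = 1e-3, adaptive_tol = 1e-3,
                            max_iterations = 1000, relaxation = 0.5,
                            linear_solver = c("cg", "direct"),
                            blend_width = 0) {
  if (linear_tol <= 0 || linear_tol >= 1) {
    stop_invalid("`linear_tol` must be in (0, 1).")
  }
  if (adaptive_tol <= 0 || adaptive_tol >= 1) {
    stop_invalid("`adaptive_tol` must be in (0, 1).")
  }
  if (max_iterations < 1) stop_invalid("`max_iterations` must be >= 1.")
  if (relaxation <= 0 || relaxation > 1) {
    stop_invalid("`relaxation` must be in (0, 1].")
  }
  structure(
    list(
      linear_tol = linear_tol, adaptive_tol = adaptive_tol,
      max_iterations = as.integer(max_iterations), relaxation = relaxation,
      linear_solver = match.arg(linear_solver), blend_width = blend_width
    ),
    class = "solver_settings"
  )
}

terminal_sets <- function(mesh, bc) {
  if (bc$swap_terminals) {
    list(
      driven_faces = mesh$ground_faces, driven_areas = mesh$ground_areas,
      ground_faces = mesh$driven_faces, ground_areas = mesh$driven_areas
    )
  } else {
    list(
      driven_faces = mesh$driven_faces, driven_areas = mesh$driven_areas,
      ground_faces = mesh$ground_faces, ground_areas = mesh$ground_areas
    )
  }
}

# nodal load vector for uniform current density over the driven faces
load_vector <- function(mesh, term, current) {
  f <- numeric(nrow(mesh$nodes))
  a_tot <- sum(term$driven_areas)
  share <- current * term$driven_areas / (4 * a_tot)
  for (c in 1:4) {
    idx <- term$driven_faces[, c]
    f[idx] <- f[idx] + share
  }
  f
}

face_mean_potential <- function(v, faces, areas) {
  face_v <- (v[faces[, 1]] + v[faces[, 2]] + v[faces[, 3]] + v[faces[, 4]]) / 4
  sum(face_v * areas) / sum(areas)
}

element_fields <- function(op, elems, v) {
  vv <- matrix(v[elems], nrow(elems), 8)
  ex <- -rowSums(op$b0x * vv)
  ey <- -rowSums(op$b0y * vv)
  ez <- -rowSums(op$b0z * vv)
  sqrt(ex^2 + ey^2 + ez^2)
}

solve_system <- function(K, f, ground_nodes, settings, x0 = NULL) {
  n <- nrow(K)
  free <- setdiff(seq_len(n), ground_nodes)
  kff <- K[free, free]
  ff <- f[free]
  if (settings$linear_solver == "direct") {
    v_free <- tryCatch(
      as.numeric(Matrix::solve(
        Matrix::Cholesky(Matrix::forceSymmetric(kff), LDL = FALSE),
        ff,
        system = "A"
      )),
      error = function(e) {
        stop_invalid(paste0(
          "Direct sparse solve failed (singular or disconnected system): ",
          conditionMessage(e)
        ))
      }
    )
    info <- list(iterations = NA_integer_, rel_residual = 0)
  } else {
    res <- pcg_solve(kff, ff,
      x0 = if (!is.null(x0)) x0[free] else NULL,
      tol = settings$linear_tol
    )
    if (res$rel_residual > settings$linear_tol) {
      stop_invalid(
        sprintf(
          "Conjugate gradients did not reach tolerance %g (relative residual %g after %d iterations).",
          settings$linear_tol, res$rel_residual, res$iterations
        ),
        class = "ectfield_convergence_error"
      )
    }
    v_free <- res$x
    info <- res[c("iterations", "rel_residual")]
  }
  v <- numeric(n)
  v[free] <- v_free
  list(v = v, info = info)
}

#' Solve the Laplace problem at fixed conductivities
#'
#' Discretizes `div(sigma grad V) = 0` on the labeled hexahedral mesh with
#' the given per-element conductivities, injects the boundary-condition
#' current uniformly over the driven terminal faces, clamps the ground
#' faces to 0 V, and reports the terminal impedance as the area-weighted
#' mean driven-face potential divided by the applied current.
#'
#' @param mesh A [build_phantom()] mesh.
#' @param conductivities Per-element conductivities (S/m), length
#'   `nrow(mesh$elems)`, all > 0 (values below 1e-15 S/m — effectively
#'   air — are clamped to that floor).
#' @param bc A [boundary_condition()].
#' @param settings A [solver_settings()].
#' @return An object of class `fem_solution`: node `potentials` (V),
#'   element `fields` (V/m, magnitude of the element-centered negative
#'   potential gradient), `conductivities`, `impedance_ohm`, linear-solver
#'   info, and the mesh.
#' @examples
#' mesh <- build_phantom(phantom_spec(inplane_size_m = 0.02))
#' sol <- solve_linear(
#'   mesh, rep(0.1, nrow(mesh$elems)),
#'   boundary_condition(2e-6), solver_settings(linear_solver = "direct")
#' )
#' sol$impedance_ohm
#' @export
solve_linear <- function(mesh, conductivities, bc = boundary_condition(),
                         settings = solver_settings()) {
  if (!inherits(mesh, "labeled_mesh")) {
    stop_invalid("`mesh` must be a labeled_mesh.")
  }
  m <- nrow(mesh$elems)
  if (length(conductivities) != m) {
    stop_invalid(sprintf(
      "`conductivities` must have one value per element (%d).", m
    ))
  }
  if (any(!is.finite(conductivities)) || any(conductivities <= 0)) {
    stop_invalid("`conductivities` must be positive and finite.")
  }
  sigma <- pmax(conductivities, 1e-15)
  op <- fem_operator(mesh)
  K <- assemble_stiffness(op, mesh$elems, sigma)
  term <- terminal_sets(mesh, bc)
  f <- load_vector(mesh, term, bc$applied_current_a)
  ground_nodes <- unique(as.vector(term$ground_faces))
  sol <- solve_system(K, f, ground_nodes, settings)
  z <- face_mean_potential(sol$v, term$driven_faces, term$driven_areas) /
    bc$applied_current_a
  structure(
    list(
      potentials = sol$v,
      fields = element_fields(op, mesh$elems, sol$v),
      conductivities = sigma,
      impedance_ohm = z,
      solver = sol$info,
      bc = bc,
      mesh = mesh
    ),
    class = "fem_solution"
  )
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf(
    "<fem_solution> %d nodes, impedance %.6g ohm at %g A\n",
    length(x$potentials), x$impedance_ohm, x$bc$applied_current_a
  ))
  invisible(x)
}

#' Discrete current through a coordinate cut plane
#'
#' Sums the external nodal currents `K v` over all nodes on the positive
#' side of the plane `coordinate > position`: by discrete current
#' conservation this equals the current crossing the plane from the
#' positive to the negative side. On a two-terminal solve a plane
#' separating the driven from the ground terminal carries the full applied
#' current; a plane separating both terminals from the passive remainder
#' carries zero net current.
#'
#' @param solution A [solve_linear()] or [solve_adaptive()] result.
#' @param position Plane position (m).
#' @param axis Coordinate axis normal to the plane: 1 (x), 2 (y) or 3 (z).
#' @return Net current (A) from the positive to the negative side.
#' @export
cut_plane_current <- function(solution, position, axis = 1) {
  mesh <- solution$mesh
  op <- fem_operator(mesh)
  K <- assemble_stiffness(op, mesh$elems, solution$conductivities)
  c_nodal <- as.numeric(K %*% solution$potentials)
  pos_side <- mesh$nodes[, axis] > position
  sum(c_nodal[pos_side])
}

resolve_tissue_sigma <- function(mesh, tissues, scalp, tf) {
  sig_map <- setNames(tissues$sigma_s_m, tissues$tissue)
  sig_map["deep_scalp"] <- scalp$deep_scalp_conductivity
  sig_map["superficial_scalp"] <- tf$floor_conductivity
  unknown <- setdiff(unique(mesh$tissue), names(sig_map))
  if (length(unknown)) {
    stop_invalid(sprintf(
      "Mesh contains tissue label(s) with no conductivity: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  sigma <- unname(sig_map[mesh$tissue])
  if (anyNA(sigma)) {
    stop_invalid("Tissue table leaves some mesh tissues without a conductivity.")
  }
  pmax(sigma, 1e-15)
}

#' Adaptive (field-dependent scalp conductivity) solve
#'
#' Fixed-point (Picard) iteration of the coupled problem in which
#' superficial-scalp conductivity depends on the local electric field:
#' starting from the transfer-function floor, each iteration solves the
#' linear problem, re-evaluates [sigma_ss()] on the element fields of the
#' superficial-scalp compartment, and under-relaxes the conductivity
#' update (`sigma <- (1 - omega) * sigma + omega * sigma_new`). Iteration
#' stops when both the relative impedance change and the largest relative
#' conductivity change fall below the adaptive tolerance, or at the
#' iteration cap (in which case the result is flagged `converged = FALSE`
#' rather than raising an error).
#'
#' At the 2 uA static test current scalp fields stay far below the
#' transfer-function threshold, so the solve reduces to the linear problem
#' with floor conductivity in one or two iterations; at the 0.9 A stimulus
#' current the scalp under and around the electrodes saturates and the
#' terminal impedance drops accordingly.
#'
#' @inheritParams solve_linear
#' @param tissues A [tissue_table()] of fixed conductivities.
#' @param scalp A [scalp_params()].
#' @param tf A [transfer_function_params()].
#' @return An object of class `adaptive_solution`: everything in
#'   [solve_linear()]'s result plus `iterations`, `converged` and a
#'   per-iteration `trace` tibble (`iteration`, `impedance_ohm`,
#'   `max_sigma_rel_change`).
#' @examples
#' mesh <- build_phantom(phantom_spec(inplane_size_m = 0.02))
#' sol <- solve_adaptive(
#'   mesh,
#'   scalp = scalp_params(0.002, 0.16),
#'   bc = boundary_condition(0.9),
#'   settings = solver_settings(linear_solver = "direct")
#' )
#' sol$impedance_ohm
#' @export
solve_adaptive <- function(mesh, tissues = tissue_table(),
                           scalp = scalp_params(0.002, 0.16),
                           tf = transfer_function_params(),
                           bc = boundary_condition(),
                           settings = solver_settings()) {
  if (!inherits(mesh, "labeled_mesh")) {
    stop_invalid("`mesh` must be a labeled_mesh.")
  }
  is_ss <- mesh$tissue == "superficial_scalp"
  if (!any(is_ss)) {
    stop_invalid("Mesh has no superficial_scalp elements to adapt.")
  }
  sigma <- resolve_tissue_sigma(mesh, tissues, scalp, tf)
  op <- fem_operator(mesh)
  term <- terminal_sets(mesh, bc)
  f <- load_vector(mesh, term, bc$applied_current_a)
  ground_nodes <- unique(as.vector(term$ground_faces))
  idx_ss <- which(is_ss)
  idx_fixed <- which(!is_ss)
  k_fixed <- assemble_stiffness(op, mesh$elems, sigma[idx_fixed], idx_fixed)

  v <- NULL
  z_prev <- NA_real_
  trace <- vector("list", settings$max_iterations)
  converged <- FALSE
  it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    K <- k_fixed + assemble_stiffness(op, mesh$elems, sigma[idx_ss], idx_ss)
    sol <- solve_system(K, f, ground_nodes, settings, x0 = v)
    v <- sol$v
    z <- face_mean_potential(v, term$driven_faces, term$driven_areas) /
      bc$applied_current_a
    fields <- element_fields(op, mesh$elems, v)
    sigma_new <- sigma_ss(
      fields[idx_ss], tf, scalp,
      blend_width = settings$blend_width
    )
    sigma_next <- (1 - settings$relaxation) * sigma[idx_ss] +
      settings$relaxation * sigma_new
    d_sigma <- max(abs(sigma_next - sigma[idx_ss]) / sigma[idx_ss])
    d_z <- if (is.na(z_prev)) Inf else abs(z - z_prev) / abs(z_prev)
    trace[[it]] <- tibble(
      iteration = it, impedance_ohm = z, max_sigma_rel_change = d_sigma
    )
    if (d_z < settings$adaptive_tol && d_sigma < settings$adaptive_tol) {
      converged <- TRUE
      break
    }
    sigma[idx_ss] <- sigma_next
    z_prev <- z
  }

  structure(
    list(
      potentials = v,
      fields = fields,
      conductivities = sigma,
      impedance_ohm = z,
      iterations = it,
      converged = converged,
      trace = dplyr::bind_rows(trace[seq_len(it)]),
      solver = sol$info,
      bc = bc,
      scalp = scalp,
      tf = tf,
      mesh = mesh
    ),
    class = c("adaptive_solution", "fem_solution")
  )
}

#' @export
print.adaptive_solution <- function(x, ...) {
  cat(sprintf(
    "<adaptive_solution> impedance %.6g ohm at %g A; %d iterations (%s)\n",
    x$impedance_ohm, x$bc$applied_current_a, x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Export a solve result to disk
#'
#' Writes a JSON summary (`impedance_ohm`, applied current, iterations,
#' convergence flag, trace) and a CSV of per-element results
#' (`element`, `tissue`, `field_v_m`, `sigma_s_m`) next to it.
#'
#' @param solution A [solve_linear()] or [solve_adaptive()] result.
#' @param path Output path for the JSON file; the CSV lands at
#'   `<path>_elements.csv`.
#' @return `path`, invisibly.
#' @export
save_solution <- function(solution, path) {
  out <- list(
    impedance_ohm = solution$impedance_ohm,
    applied_current_a = solution$bc$applied_current_a,
    iterations = solution$iterations %||% 1L,
    converged = solution$converged %||% TRUE
  )
  if (!is.null(solution$trace)) out$trace <- solution$trace
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  readr::write_csv(
    tibble(
      element = seq_along(solution$fields),
      tissue = solution$mesh$tissue,
      field_v_m = solution$fields,
      sigma_s_m = solution$conductivities
    ),
    paste0(tools::file_path_sans_ext(path), "_elements.csv")
  )
  invisible(path)
}
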