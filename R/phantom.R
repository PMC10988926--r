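# Synthetic multilayer head phantoms: a layered slab (default; admits an
# analytic series-resistance oracle) and concentric shells built on a
# radially projected cube lattice (adds curvature). Both carry the same
# outside-in tissue stack and two rectangular gel pad electrodes on the
# outer surface.

SLAB_LAYER_ORDER <- c(
  "superficial_scalp", "deep_scalp", "skull", "csf",
  "gray_matter", "white_matter"
)

# VTK hexahedron node ordering: bottom quad counter-clockwise, then top quad.
HEX_BOTTOM <- 1:4
HEX_TOP <- 5:8

#' Default phantom layer stacks
#'
#' The default outside-in tissue stack: superficial scalp 3.5 mm, deep
#' scalp 3.5 mm (the scalp is bisected into its two compartments), skull
#' 7 mm, CSF/meninges 3 mm, gray matter 4 mm, white matter 6 mm. For the
#' shell phantom the same thicknesses hang off a 92 mm outer radius, with
#' an unmeshed interior cavity.
#'
#' @return A tibble with columns `tissue` and `thickness_m` (slab) or
#'   `outer_radius_m` (shells).
#' @export
default_slab_layers <- function() {
  tibble(
    tissue = SLAB_LAYER_ORDER,
    thickness_m = c(0.0035, 0.0035, 0.007, 0.003, 0.004, 0.006)
  )
}

#' @rdname default_slab_layers
#' @param outer_radius_m Outer (superficial scalp) radius in meters.
#' @export
default_shell_layers <- function(outer_radius_m = 0.092) {
  th <- default_slab_layers()$thickness_m
  tibble(
    tissue = SLAB_LAYER_ORDER,
    outer_radius_m = outer_radius_m - cumsum(c(0, th[-length(th)]))
  )
}

#' Specify a synthetic head phantom
#'
#' Describes a multilayer volume-conductor geometry with two rectangular
#' pad electrodes (adhesive gel pads, default 4.2 cm x 4.9 cm x 1.7 mm)
#' on the outer surface, to be meshed by [build_phantom()].
#'
#' Two shapes are available. `"layered_slab"` stacks the six tissue layers
#' as flat slabs with both electrodes on the top face — the plain series
#' current path from gel through scalp and skull, with an analytic
#' resistance oracle for uniform conductivity. `"concentric_shells"` wraps
#' the same stack into spherical shells (nodes on a radially projected
#' cube lattice) around an interior cavity, adding surface curvature.
#'
#' @param shape `"layered_slab"` or `"concentric_shells"`.
#' @param layers Outside-in tissue stack: a tibble with columns `tissue`
#'   and `thickness_m` (slab) or `outer_radius_m` (shells). Defaults to
#'   [default_slab_layers()] / [default_shell_layers()].
#' @param extent_m Slab only: lateral extent `c(Lx, Ly)` in meters.
#' @param electrode_centers Slab: a 2 x 2 matrix of patch centers (x, y) on
#'   the top face, meters. Shells: a length-2 vector of angular centers
#'   (radians, on the great circle through both patches, default
#'   `c(-0.5, 0.5)`).
#' @param electrode_size Patch footprint `c(width, height)` in meters.
#' @param gel_thickness_m Gel pad thickness (m).
#' @param element_size_m Target element size through the layer stack (m);
#'   must not exceed half the thinnest layer so every layer is resolved by
#'   at least two elements.
#' @param inplane_size_m Target element size along the surface (m);
#'   defaults to `element_size_m`. Surface resolution is decoupled from the
#'   layer-resolving size because impedance converges much faster laterally
#'   than through the thin-layer stack.
#' @param inner_radius_m Shells only: cavity radius (m).
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec() # default bifrontal slab
#' @export
phantom_spec <- function(shape = c("layered_slab", "concentric_shells"),
                         layers = NULL,
                         extent_m = c(0.14, 0.075),
                         electrode_centers = NULL,
                         electrode_size = c(0.042, 0.049),
                         gel_thickness_m = 0.0017,
                         element_size_m = 0.0015,
                         inplane_size_m = 0.007,
                         inner_radius_m = 0.055) {
  shape <- match.arg(shape)
  if (is.null(layers)) {
    layers <- if (shape == "layered_slab") {
      default_slab_layers()
    } else {
      default_shell_layers()
    }
  }
  layers <- as_tibble(layers)
  if (!identical(layers$tissue, SLAB_LAYER_ORDER)) {
    stop_invalid(sprintf(
      "`layers` must list the six tissues outside-in: %s.",
      paste(SLAB_LAYER_ORDER, collapse = ", ")
    ))
  }
  check_scalar_positive(gel_thickness_m, "gel_thickness_m")
  check_scalar_positive(element_size_m, "element_size_m")
  inplane_size_m <- inplane_size_m %||% element_size_m
  check_scalar_positive(inplane_size_m, "inplane_size_m")
  if (any(electrode_size <= 0) || length(electrode_size) != 2L) {
    stop_invalid("`electrode_size` must be two positive lengths (m).")
  }

  if (shape == "layered_slab") {
    if (!"thickness_m" %in% names(layers)) {
      stop_invalid("Slab `layers` need a `thickness_m` column.")
    }
    thick <- layers$thickness_m
    if (any(thick <= 0)) stop_invalid("Layer thicknesses must be positive.")
    if (element_size_m > min(thick) / 2 + 1e-12) {
      stop_invalid(sprintf(
        "`element_size_m` (%g m) exceeds half the thinnest layer (%s, %g m): every layer must be resolved by at least 2 elements.",
        element_size_m, layers$tissue[which.min(thick)], min(thick)
      ))
    }
    if (length(extent_m) != 2L || any(extent_m <= 0)) {
      stop_invalid("`extent_m` must be two positive lengths (m).")
    }
    if (is.null(electrode_centers)) {
      # bilateral pads straddling the midline with a 2 cm gap
      gap <- 0.02
      cx <- extent_m[1] / 2 + c(-1, 1) * (gap + electrode_size[1]) / 2
      electrode_centers <- cbind(cx, rep(extent_m[2] / 2, 2))
    }
    electrode_centers <- matrix(as.numeric(electrode_centers), ncol = 2)
    if (nrow(electrode_centers) != 2L) {
      stop_invalid("`electrode_centers` must give exactly two patch centers.")
    }
    half <- electrode_size / 2
    for (p in 1:2) {
      lo <- electrode_centers[p, ] - half
      hi <- electrode_centers[p, ] + half
      if (any(lo < -1e-12) || hi[1] > extent_m[1] + 1e-12 ||
        hi[2] > extent_m[2] + 1e-12) {
        stop_invalid(sprintf(
          "Electrode patch %d extends off the phantom surface.", p
        ))
      }
    }
    x_ranges <- cbind(
      electrode_centers[, 1] - half[1],
      electrode_centers[, 1] + half[1]
    )
    y_ranges <- cbind(
      electrode_centers[, 2] - half[2],
      electrode_centers[, 2] + half[2]
    )
    overlap_x <- min(x_ranges[, 2]) - max(x_ranges[, 1]) > 1e-12
    overlap_y <- min(y_ranges[, 2]) - max(y_ranges[, 1]) > 1e-12
    if (overlap_x && overlap_y) {
      stop_invalid("Electrode patches overlap.")
    }
  } else {
    if (!"outer_radius_m" %in% names(layers)) {
      stop_invalid("Shell `layers` need an `outer_radius_m` column.")
    }
    radii <- layers$outer_radius_m
    if (any(diff(radii) >= 0)) {
      stop_invalid("Shell outer radii must decrease outside-in.")
    }
    check_scalar_positive(inner_radius_m, "inner_radius_m")
    if (inner_radius_m >= min(radii)) {
      stop_invalid("`inner_radius_m` must sit inside the innermost layer.")
    }
    thick <- -diff(c(radii, inner_radius_m))
    if (element_size_m > min(thick[seq_len(nrow(layers) - 1)]) / 2 + 1e-12) {
      stop_invalid(
        "`element_size_m` exceeds half the thinnest shell layer: every layer must be resolved by at least 2 elements."
      )
    }
    if (is.null(electrode_centers)) electrode_centers <- c(-0.5, 0.5)
    if (length(electrode_centers) != 2L) {
      stop_invalid("Shell `electrode_centers` must be two angles (radians).")
    }
    r_out <- radii[1]
    half_ang <- electrode_size / (2 * r_out)
    if (abs(electrode_centers[2] - electrode_centers[1]) < 2 * half_ang[1]) {
      stop_invalid("Electrode patches overlap.")
    }
  }

  structure(
    list(
      shape = shape, layers = layers, extent_m = extent_m,
      electrode_centers = electrode_centers,
      electrode_size = electrode_size,
      gel_thickness_m = gel_thickness_m,
      element_size_m = element_size_m,
      inplane_size_m = inplane_size_m,
      inner_radius_m = inner_radius_m
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %s, %d layers, element size %g mm (in-plane %g mm)\n",
    x$shape, nrow(x$layers), x$element_size_m * 1e3, x$inplane_size_m * 1e3
  ))
  invisible(x)
}

# subdivide [a, b] segments defined by `breaks` into pieces of at most h
refine_breaks <- function(breaks, h) {
  breaks <- sort(unique(breaks))
  out <- breaks[1]
  for (i in seq_len(length(breaks) - 1L)) {
    len <- breaks[i + 1L] - breaks[i]
    n <- max(1L, ceiling(len / h - 1e-9))
    out <- c(out, breaks[i] + len * seq_len(n) / n)
  }
  out
}

# per-layer z levels (bottom-up), >= 2 elements per layer
layer_levels <- function(thicknesses, h, min_div = 2L) {
  z <- 0
  layer_of <- integer(0)
  for (i in seq_along(thicknesses)) {
    n <- max(min_div, ceiling(thicknesses[i] / h - 1e-9))
    z <- c(z, tail(z, 1) + thicknesses[i] * seq_len(n) / n)
    layer_of <- c(layer_of, rep(i, n))
  }
  list(levels = z, layer_of = layer_of)
}

quad_areas <- function(nodes, faces) {
  d1 <- nodes[faces[, 3], , drop = FALSE] - nodes[faces[, 1], , drop = FALSE]
  d2 <- nodes[faces[, 4], , drop = FALSE] - nodes[faces[, 2], , drop = FALSE]
  cx <- d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2]
  cy <- d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3]
  cz <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

new_labeled_mesh <- function(nodes, elems, tissue, driven_faces, ground_faces,
                             shape, spec = NULL) {
  used <- sort(unique(c(elems, driven_faces, ground_faces)))
  remap <- integer(nrow(nodes))
  remap[used] <- seq_along(used)
  mesh <- structure(
    list(
      nodes = nodes[used, , drop = FALSE],
      elems = matrix(remap[elems], ncol = 8),
      tissue = tissue,
      driven_faces = matrix(remap[driven_faces], ncol = 4),
      ground_faces = matrix(remap[ground_faces], ncol = 4),
      shape = shape,
      spec = spec
    ),
    class = "labeled_mesh"
  )
  mesh$driven_areas <- quad_areas(mesh$nodes, mesh$driven_faces)
  mesh$ground_areas <- quad_areas(mesh$nodes, mesh$ground_faces)
  stopifnot(
    nrow(mesh$elems) == length(tissue),
    nrow(mesh$driven_faces) > 0, nrow(mesh$ground_faces) > 0
  )
  mesh
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf(
    "<labeled_mesh> %s: %d nodes, %d hexahedral elements\n",
    x$shape, nrow(x$nodes), nrow(x$elems)
  ))
  tab <- table(x$tissue)
  cat("  elements per tissue:",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf(
    "  terminal faces: %d driven, %d ground\n",
    nrow(x$driven_faces), nrow(x$ground_faces)
  ))
  invisible(x)
}

build_slab_phantom <- function(spec) {
  half <- spec$electrode_size / 2
  ec <- spec$electrode_centers
  xb <- c(0, spec$extent_m[1], ec[, 1] - half[1], ec[, 1] + half[1])
  yb <- c(0, spec$extent_m[2], ec[, 2] - half[2], ec[, 2] + half[2])
  xg <- refine_breaks(xb, spec$inplane_size_m)
  yg <- refine_breaks(yb, spec$inplane_size_m)

  # bottom-up stacking: reverse the outside-in layer list
  th_bu <- rev(spec$layers$thickness_m)
  tis_bu <- rev(spec$layers$tissue)
  zz <- layer_levels(th_bu, spec$element_size_m)
  n_base_lev <- length(zz$levels)
  gel_div <- max(1L, ceiling(spec$gel_thickness_m / spec$element_size_m - 1e-9))
  z_top <- tail(zz$levels, 1)
  zg <- c(zz$levels, z_top + spec$gel_thickness_m * seq_len(gel_div) / gel_div)

  nx <- length(xg); ny <- length(yg); nz <- length(zg)
  nodes <- cbind(
    rep(xg, times = ny * nz),
    rep(rep(yg, each = nx), times = nz),
    rep(zg, each = nx * ny)
  )
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny

  xc <- (xg[-1] + xg[-nx]) / 2
  yc <- (yg[-1] + yg[-ny]) / 2
  in_patch <- function(p) {
    outer(
      xc >= ec[p, 1] - half[1] - 1e-12 & xc <= ec[p, 1] + half[1] + 1e-12,
      yc >= ec[p, 2] - half[2] - 1e-12 & yc <= ec[p, 2] + half[2] + 1e-12,
      "&"
    )
  }
  patch1 <- in_patch(1); patch2 <- in_patch(2)

  ii <- rep(seq_len(nx - 1L), times = ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  column_hex <- function(k) {
    cbind(
      nid(ii, jj, k), nid(ii + 1L, jj, k),
      nid(ii + 1L, jj + 1L, k), nid(ii, jj + 1L, k),
      nid(ii, jj, k + 1L), nid(ii + 1L, jj, k + 1L),
      nid(ii + 1L, jj + 1L, k + 1L), nid(ii, jj + 1L, k + 1L)
    )
  }

  elems <- vector("list", nz - 1L)
  tissue <- vector("list", nz - 1L)
  gel_cols <- as.vector(patch1 | patch2)
  for (k in seq_len(nz - 1L)) {
    hexes <- column_hex(k)
    if (k < n_base_lev) {
      elems[[k]] <- hexes
      tissue[[k]] <- rep(tis_bu[zz$layer_of[k]], nrow(hexes))
    } else {
      elems[[k]] <- hexes[gel_cols, , drop = FALSE]
      tissue[[k]] <- rep("gel", sum(gel_cols))
    }
  }
  elems <- do.call(rbind, elems)
  tissue <- unlist(tissue)

  top_face <- function(patch) {
    sel <- as.vector(patch)
    cbind(
      nid(ii, jj, nz)[sel], nid(ii + 1L, jj, nz)[sel],
      nid(ii + 1L, jj + 1L, nz)[sel], nid(ii, jj + 1L, nz)[sel]
    )
  }
  mesh <- new_labeled_mesh(
    nodes, elems, tissue,
    driven_faces = top_face(patch1), ground_faces = top_face(patch2),
    shape = "layered_slab", spec = spec
  )
  mesh$grid <- list(x = xg, y = yg, z = zg, n_base_levels = n_base_lev)
  mesh
}

# cube-surface lattice: boundary points of an (n+1)^3 lattice on [-1,1]^3,
# radially projected onto spheres. Shared edges/corners dedupe naturally.
cube_surface <- function(n) {
  s <- seq(-1, 1, length.out = n + 1L)
  grid <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  on_b <- grid$i %in% c(0L, n) | grid$j %in% c(0L, n) | grid$k %in% c(0L, n)
  pts <- grid[on_b, ]
  key <- sprintf("%d_%d_%d", pts$i, pts$j, pts$k)
  idx <- setNames(seq_len(nrow(pts)), key)
  kk <- function(i, j, k) idx[sprintf("%d_%d_%d", i, j, k)]

  faces <- list()
  ij <- expand.grid(a = 0:(n - 1L), b = 0:(n - 1L))
  a <- ij$a; b <- ij$b
  add <- function(q) faces[[length(faces) + 1L]] <<- q
  add(cbind(kk(n, a, b), kk(n, a + 1L, b), kk(n, a + 1L, b + 1L), kk(n, a, b + 1L)))   # +x
  add(cbind(kk(0L, a, b), kk(0L, a, b + 1L), kk(0L, a + 1L, b + 1L), kk(0L, a + 1L, b))) # -x
  add(cbind(kk(a, n, b), kk(a, n, b + 1L), kk(a + 1L, n, b + 1L), kk(a + 1L, n, b)))   # +y
  add(cbind(kk(a, 0L, b), kk(a + 1L, 0L, b), kk(a + 1L, 0L, b + 1L), kk(a, 0L, b + 1L))) # -y
  add(cbind(kk(a, b, n), kk(a + 1L, b, n), kk(a + 1L, b + 1L, n), kk(a, b + 1L, n)))   # +z
  add(cbind(kk(a, b, 0L), kk(a, b + 1L, 0L), kk(a + 1L, b + 1L, 0L), kk(a + 1L, b, 0L))) # -z
  quads <- do.call(rbind, faces)

  xyz <- cbind(
    -1 + 2 * pts$i / n, -1 + 2 * pts$j / n, -1 + 2 * pts$k / n
  )
  dirs <- xyz / sqrt(rowSums(xyz^2))
  list(dirs = dirs, quads = unname(quads))
}

build_shell_phantom <- function(spec) {
  radii <- spec$layers$outer_radius_m
  r_out <- radii[1]
  n <- max(6L, ceiling((pi / 2 * r_out) / spec$inplane_size_m))
  surf <- cube_surface(n)
  n_surf <- nrow(surf$dirs)

  # radial levels inside-out; innermost layer extends down to the cavity
  th_io <- rev(-diff(c(radii, spec$inner_radius_m)))
  tis_io <- rev(spec$layers$tissue)
  zz <- layer_levels(th_io, spec$element_size_m)
  r_lev <- spec$inner_radius_m + zz$levels
  n_lev <- length(r_lev)
  gel_div <- max(1L, ceiling(spec$gel_thickness_m / spec$element_size_m - 1e-9))
  r_all <- c(r_lev, r_out + spec$gel_thickness_m * seq_len(gel_div) / gel_div)

  nodes <- do.call(rbind, lapply(r_all, function(r) surf$dirs * r))
  off <- function(lev) (lev - 1L) * n_surf

  # patch selection on the great circle in the x-z plane: angle from +z axis
  ctr <- (surf$dirs[surf$quads[, 1], ] + surf$dirs[surf$quads[, 2], ] +
    surf$dirs[surf$quads[, 3], ] + surf$dirs[surf$quads[, 4], ]) / 4
  ctr <- ctr / sqrt(rowSums(ctr^2))
  ang_u <- atan2(ctr[, 1], ctr[, 3]) # along-circle angle
  ang_v <- asin(pmin(1, pmax(-1, ctr[, 2]))) # transverse angle
  half_ang <- spec$electrode_size / (2 * r_out)
  sel_patch <- function(a0) {
    abs(ang_u - a0) <= half_ang[1] & abs(ang_v) <= half_ang[2]
  }
  p1 <- sel_patch(spec$electrode_centers[1])
  p2 <- sel_patch(spec$electrode_centers[2])
  if (!any(p1) || !any(p2)) {
    stop_invalid("Electrode patches select no surface cells; refine the mesh or enlarge the patches.")
  }
  if (any(p1 & p2)) stop_invalid("Electrode patches overlap.")

  n_quad <- nrow(surf$quads)
  elems <- vector("list", length(r_all) - 1L)
  tissue <- vector("list", length(r_all) - 1L)
  gel_cells <- p1 | p2
  for (k in seq_len(length(r_all) - 1L)) {
    hexes <- cbind(surf$quads + off(k), surf$quads + off(k + 1L))
    if (k < n_lev) {
      elems[[k]] <- hexes
      tissue[[k]] <- rep(tis_io[zz$layer_of[k]], n_quad)
    } else {
      elems[[k]] <- hexes[gel_cells, , drop = FALSE]
      tissue[[k]] <- rep("gel", sum(gel_cells))
    }
  }
  elems <- do.call(rbind, elems)
  tissue <- unlist(tissue)

  outer_quads <- surf$quads + off(length(r_all))
  mesh <- new_labeled_mesh(
    nodes, elems, tissue,
    driven_faces = outer_quads[p1, , drop = FALSE],
    ground_faces = outer_quads[p2, , drop = FALSE],
    shape = "concentric_shells", spec = spec
  )
  mesh$grid <- list(n_surface = n, radial_levels = r_all)
  mesh
}

#' Build a layered column with full-face terminals
#'
#' A verification geometry: a rectangular column of stacked tissue layers
#' with the driven terminal covering the entire top face and ground
#' covering the entire bottom face. Current flow is uniform and purely
#' vertical, so the impedance has the closed form
#' `sum(thickness / (sigma * area))` — the series-resistance oracle used
#' to validate the FEM path.
#'
#' @param layers Tibble with columns `tissue` and `thickness_m`, listed
#'   top-down. Any [tissue_table()] labels are allowed here (the canonical
#'   six-layer ordering is not enforced for this diagnostic geometry).
#' @param cross_section_m Lateral extent `c(Lx, Ly)` in meters.
#' @param element_size_m Vertical element size target (m).
#' @param inplane_size_m Lateral element size target (m).
#' @return A `labeled_mesh` with full-face terminal sets.
#' @examples
#' mesh <- column_phantom(
#'   tibble::tibble(tissue = "skull", thickness_m = 0.01),
#'   cross_section_m = c(0.01, 0.01)
#' )
#' @export
column_phantom <- function(layers,
                           cross_section_m = c(0.01, 0.01),
                           element_size_m = min(layers$thickness_m) / 2,
                           inplane_size_m = max(cross_section_m) / 4) {
  layers <- as_tibble(layers)
  if (!all(c("tissue", "thickness_m") %in% names(layers)) ||
    any(layers$thickness_m <= 0)) {
    stop_invalid("`layers` needs `tissue` and positive `thickness_m` columns.")
  }
  unknown <- setdiff(layers$tissue, tissue_table()$tissue)
  if (length(unknown)) {
    stop_invalid(sprintf(
      "Unknown tissue label(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  xg <- refine_breaks(c(0, cross_section_m[1]), inplane_size_m)
  yg <- refine_breaks(c(0, cross_section_m[2]), inplane_size_m)
  zz <- layer_levels(rev(layers$thickness_m), element_size_m, min_div = 1L)
  zg <- zz$levels
  tis_bu <- rev(layers$tissue)
  nx <- length(xg); ny <- length(yg); nz <- length(zg)
  nodes <- cbind(
    rep(xg, times = ny * nz),
    rep(rep(yg, each = nx), times = nz),
    rep(zg, each = nx * ny)
  )
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ii <- rep(seq_len(nx - 1L), times = ny - 1L)
  jj <- rep(seq_len(ny - 1L), each = nx - 1L)
  elems <- vector("list", nz - 1L)
  for (k in seq_len(nz - 1L)) {
    elems[[k]] <- cbind(
      nid(ii, jj, k), nid(ii + 1L, jj, k),
      nid(ii + 1L, jj + 1L, k), nid(ii, jj + 1L, k),
      nid(ii, jj, k + 1L), nid(ii + 1L, jj, k + 1L),
      nid(ii + 1L, jj + 1L, k + 1L), nid(ii, jj + 1L, k + 1L)
    )
  }
  tissue <- rep(tis_bu[zz$layer_of], each = (nx - 1L) * (ny - 1L))
  face_at <- function(k) {
    cbind(nid(ii, jj, k), nid(ii + 1L, jj, k),
      nid(ii + 1L, jj + 1L, k), nid(ii, jj + 1L, k))
  }
  new_labeled_mesh(
    nodes, do.call(rbind, elems), tissue,
    driven_faces = face_at(nz), ground_faces = face_at(1L),
    shape = "column"
  )
}

#' Mesh a phantom specification
#'
#' Builds the labeled hexahedral mesh: tissue layers plus gel pad volumes
#' appended above the outer surface at the two electrode patches, with the
#' driven and ground terminal face sets on the outer gel faces. All
#' coordinates are meters; element tissue labels are the [tissue_table()]
#' names.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `labeled_mesh`: node coordinates (`nodes`,
#'   N x 3), hexahedral connectivity (`elems`, M x 8, 1-based), per-element
#'   `tissue` labels, and terminal face sets `driven_faces` /
#'   `ground_faces` with areas.
#' @examples
#' mesh <- build_phantom(phantom_spec(inplane_size_m = 0.02))
#' mesh
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    stop_invalid("`spec` must be created with phantom_spec().")
  }
  switch(spec$shape,
    layered_slab = build_slab_phantom(spec),
    concentric_shells = build_shell_phantom(spec)
  )
}

#' Element volumes by tissue
#'
#' Integrates each trilinear hexahedron's Jacobian (2x2x2 Gauss rule) and
#' sums volumes per tissue label.
#'
#' @param mesh A [build_phantom()] mesh.
#' @return A tibble with columns `tissue` and `volume_m3`.
#' @export
mesh_volumes <- function(mesh) {
  vols <- element_volumes(mesh)
  out <- tapply(vols, mesh$tissue, sum)
  tibble(tissue = names(out), volume_m3 = as.numeric(out))
}

#' Read / write labeled meshes (legacy VTK)
#'
#' `write_mesh()` writes an ASCII legacy-VTK unstructured grid (hexahedra,
#' `CELL_DATA` scalar `tissue_id`) plus a JSON sidecar `<path>.json`
#' holding the id-to-label map and the terminal face sets; `read_mesh()`
#' reads that pair back. The round trip preserves connectivity,
#' coordinates (full double precision), labels and terminals. Reading a
#' file whose labels are not all known [tissue_table()] tissues, or whose
#' cell data does not cover every cell, is an error.
#'
#' @param mesh A [build_phantom()] mesh.
#' @param path Path to the `.vtk` file.
#' @return `read_mesh()` returns a `labeled_mesh`; `write_mesh()` returns
#'   `path` invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (!inherits(mesh, "labeled_mesh")) {
    stop_invalid("`mesh` must be a labeled_mesh.")
  }
  labels <- sort(unique(mesh$tissue))
  id_of <- setNames(seq_along(labels) - 1L, labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "ectfield labeled head phantom",
    "ASCII",
    "DATASET UNSTRUCTURED_GRID",
    sprintf("POINTS %d double", nrow(mesh$nodes))
  ), con)
  writeLines(apply(format(mesh$nodes, digits = 17, trim = TRUE, scientific = TRUE), 1, paste, collapse = " "), con)
  m <- nrow(mesh$elems)
  writeLines(sprintf("CELLS %d %d", m, m * 9L), con)
  writeLines(paste(8L, apply(mesh$elems - 1L, 1, paste, collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(12L, m)), con)
  writeLines(c(
    sprintf("CELL_DATA %d", m),
    "SCALARS tissue_id int 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(as.character(id_of[mesh$tissue]), con)
  jsonlite::write_json(
    list(
      tissue_ids = as.list(id_of),
      shape = mesh$shape,
      driven_faces = mesh$driven_faces - 1L,
      ground_faces = mesh$ground_faces - 1L
    ),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("No such file: %s", path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_invalid(sprintf("Missing mesh sidecar: %s", sidecar))
  }
  lines <- readLines(path)
  find1 <- function(pat) {
    i <- grep(pat, lines)
    if (!length(i)) stop_invalid(sprintf("Not a supported VTK file (missing '%s'): %s", pat, path))
    i[1]
  }
  ip <- find1("^POINTS ")
  n_pts <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(
    as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + n_pts)]), "\\s+"))),
    ncol = 3, byrow = TRUE
  )
  ic <- find1("^CELLS ")
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_rows <- strsplit(trimws(lines[(ic + 1):(ic + m)]), "\\s+")
  counts <- vapply(cell_rows, function(r) as.integer(r[1]), integer(1))
  if (any(counts != 8L)) {
    stop_invalid("Only hexahedral (8-node) cells are supported.")
  }
  elems <- matrix(
    as.integer(unlist(lapply(cell_rows, function(r) r[-1]))),
    ncol = 8, byrow = TRUE
  ) + 1L
  find1("^CELL_DATA ")
  isc <- grep("^SCALARS tissue_id", lines)
  if (!length(isc)) stop_invalid("Mesh file has no `tissue_id` cell data: cells lack labels.")
  ids_start <- isc[1] + 2L # skip LOOKUP_TABLE line
  id_lines <- lines[ids_start:length(lines)]
  id_lines <- id_lines[nzchar(trimws(id_lines))]
  ids <- suppressWarnings(as.integer(unlist(strsplit(trimws(id_lines), "\\s+"))))
  if (length(ids) < m || anyNA(ids[seq_len(m)])) {
    stop_invalid(sprintf(
      "Cell data covers %d of %d cells: some cells lack a tissue label.",
      sum(!is.na(ids)), m
    ))
  }
  ids <- ids[seq_len(m)]
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  id_map <- unlist(side$tissue_ids)
  label_of <- setNames(names(id_map), as.character(id_map))
  tissue <- unname(label_of[as.character(ids)])
  known <- tissue_table()$tissue
  unknown <- setdiff(unique(c(tissue, names(id_map))), c(known, NA))
  if (anyNA(tissue) || length(unknown)) {
    bad <- unique(c(unknown, as.character(ids[is.na(tissue)])))
    stop_invalid(sprintf(
      "Unknown tissue label(s) in %s: %s.", path, paste(bad, collapse = ", ")
    ))
  }
  mesh <- structure(
    list(
      nodes = nodes, elems = elems, tissue = tissue,
      driven_faces = matrix(as.integer(unlist(side$driven_faces)), ncol = 4) + 1L,
      ground_faces = matrix(as.integer(unlist(side$ground_faces)), ncol = 4) + 1L,
      shape = side$shape %||% "unknown", spec = NULL
    ),
    class = "labeled_mesh"
  )
  mesh$driven_areas <- quad_areas(mesh$nodes, mesh$driven_faces)
  mesh$ground_areas <- quad_areas(mesh$nodes, mesh$ground_faces)
  mesh
}
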