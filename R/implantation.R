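# ICRS parameterization and the in-silico implantation procedure: carve the
# tunnel, map its boundary nodes onto the triangular ring cross-section,
# bind the ring outline as a rigid body and let it settle axially under IOP
# and pre-strain.

#' Define a ring segment design
#'
#' A ring segment spanning `arc_length` degrees whose triangular
#' cross-section varies linearly along the arc: thickness (triangle height)
#' between `thickness[1]` at 0 deg and `thickness[2]` at `arc_length`, base
#' width likewise.  The default reproduces an asymmetric design with
#' thickness 150-300 um and base 600-800 um over a 160 deg arc; fixing one
#' (or both) ranges yields the hypothetical thickness-only, base-only and
#' symmetric comparison designs.
#'
#' @param arc_length arc length in degrees.
#' @param thickness length-2 numeric, um, values at the two ends (may be
#'   equal).
#' @param base length-2 numeric, um.
#' @param name optional design label.
#' @return object of class `ring_design`.
#' @examples
#' ring_design()                                   # asymmetric 150-300/600-800
#' ring_design(thickness = c(150, 300), base = c(700, 700))  # thickness-only
#' @export
ring_design <- function(arc_length = 160, thickness = c(150, 300),
                        base = c(600, 800), name = NULL) {
  stopifnot(arc_length > 0, length(thickness) == 2, length(base) == 2,
            all(thickness > 0), all(base > 0))
  structure(list(arc_length = arc_length,
                 thickness = thickness, base = base,
                 name = name %||% "ring"),
            class = "ring_design")
}

#' @export
print.ring_design <- function(x, ...) {
  cat(sprintf(
    "<ring_design %s> arc %g deg, thickness %g-%g um, base %g-%g um\n",
    x$name, x$arc_length, x$thickness[1], x$thickness[2],
    x$base[1], x$base[2]))
  invisible(x)
}

#' The four study designs
#'
#' Asymmetric (thickness and base varying), thickness-only (base fixed
#' 700 um), base-only (thickness fixed 225 um) and a symmetric clinical
#' reference (225 um / 600 um).
#'
#' @return named list of [ring_design()] objects.
#' @export
study_designs <- function() {
  list(
    asymmetric = ring_design(name = "asymmetric"),
    thickness_only = ring_design(thickness = c(150, 300),
                                 base = c(700, 700),
                                 name = "thickness_only"),
    base_only = ring_design(thickness = c(225, 225), base = c(600, 800),
                            name = "base_only"),
    symmetric = ring_design(thickness = c(225, 225), base = c(600, 600),
                            name = "symmetric"))
}

#' Ring cross-section at an angular position
#'
#' Linear interpolation of thickness and base width along the arc, with the
#' closed triangular outline (base on the tunnel floor, apex pointing
#' anteriorly) in local tunnel coordinates.
#'
#' @param design a [ring_design()].
#' @param angle angular position in degrees, in `[0, arc_length]`.
#' @return object of class `cross_section` with fields `thickness`, `base`
#'   (um) and `outline` (closed 3-vertex polyline, um).
#' @export
ring_cross_section <- function(design, angle) {
  if (angle < 0 || angle > design$arc_length)
    stop("angle outside the ring arc")
  s <- angle / design$arc_length
  th <- design$thickness[1] + s * diff(design$thickness)
  b <- design$base[1] + s * diff(design$base)
  outline <- rbind(c(-b / 2, 0), c(b / 2, 0), c(0, th), c(-b / 2, 0))
  colnames(outline) <- c("xi", "eta")
  structure(list(thickness = th, base = b, angle = angle,
                 outline = outline, design = design$name),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf(
    "<cross_section> %s @ %g deg: thickness %.0f um, base %.0f um\n",
    x$design, x$angle, x$thickness, x$base))
  invisible(x)
}

# Map a point (xi um along tunnel, eta um above floor) of the tunnel
# rectangle onto the triangular cross-section.  Nodes keep their tangential
# station (the ring does not drag tissue along the tunnel); when the base
# exceeds the tunnel width the extra width is taken up entirely on the
# inner (axis-facing, negative-xi) edge, realized as a linear inward
# stretch of the inner half of the tunnel.  Returns the mapped coordinates
# and a contact flag; nodes outside the ring base are not in contact and
# must be left free.
triangle_map <- function(xi, eta, w, h, b, th) {
  if (b > w) {
    base_left <- -w / 2 - (b - w)
    xi2 <- ifelse(xi < 0, xi * (-base_left) / (w / 2), xi)
    base_right <- w / 2
  } else {
    base_left <- -b / 2
    base_right <- b / 2
    xi2 <- xi
  }
  apex_xi <- (base_left + base_right) / 2
  half_l <- apex_xi - base_left
  half_r <- base_right - apex_xi
  height <- th * pmin(pmax(0, (xi2 - base_left) / half_l),
                      pmax(0, (base_right - xi2) / half_r))
  contact <- xi2 >= base_left - 1e-9 & xi2 <= base_right + 1e-9
  eta2 <- (eta / h) * height
  cbind(xi = xi2, eta = eta2, contact = as.numeric(contact))
}

#' Impose a ring cross-section on the carved tunnel
#'
#' Maps every node of the tunnel block onto the triangular ring outline in
#' the curved tunnel frame (arc position along the tunnel mid-depth, height
#' above the local tunnel floor) and returns the prescribed-displacement set
#' together with the node set forming the ring's outer border, ready for
#' rigid binding.
#'
#' @param mesh a carved `cornea_mesh` (tunnel elements inactive).
#' @param cs a [ring_cross_section()].
#' @param tunnel the [tunnel_spec()] used when meshing (defaults to the
#'   mesh's).
#' @return list with `targets` (tibble: node, ux, uy, boundary flag),
#'   `rigid` (a [rigid_body_constraint()] on the boundary outline with the
#'   axial dof free), and `prescribed` (data frame for the orphaned interior
#'   nodes).
#' @export
impose_ring <- function(mesh, cs, tunnel = mesh$tunnel) {
  if (any(mesh$active[mesh$element_sets$tunnel]))
    stop("impose_ring requires a carved mesh (see carve_tunnel)")
  geometry <- mesh$geometry
  w <- tunnel$width; h <- tunnel$height
  # the inner-edge expansion absorbs any base overhang; still guard against
  # cross-sections far larger than the tunnel can embed without inversion
  if (cs$base > 2 * w)
    stop("cross-section too wide to embed in the tunnel footprint")
  a_c <- tunnel_center_alpha(geometry, tunnel)
  tot_c <- normal_depth_to_posterior(geometry, a_c)
  d_mid <- tunnel$depth_fraction * tot_c + 0.5 * h / UM_PER_MM
  r_mid <- geometry$r_anterior - d_mid
  nodes <- mesh$node_sets$tunnel
  al <- mesh$node_alpha[nodes]
  dep <- mesh$node_depth[nodes]
  # rectangle parameters (um) of each tunnel node in the meshed (curved)
  # footprint: xi along the tunnel at mid-depth radius, eta height above the
  # local tunnel floor
  tot <- vapply(al, function(a) normal_depth_to_posterior(geometry, a),
                numeric(1))
  floor_depth <- tunnel$depth_fraction * tot + h / UM_PER_MM
  xi <- (al - a_c) * r_mid * UM_PER_MM
  eta <- (floor_depth - dep) * UM_PER_MM
  mapped <- triangle_map(xi, eta, w, h, cs$base, cs$thickness)
  # target positions on the straight-edged triangle in the meridional plane:
  # the implant is a rigid body, so its cross-section does not bend with the
  # corneal curvature.  Local frame at the tunnel floor center: tangent
  # (away from the apex) and anterior-pointing normal.
  f_center <- point_at_depth(geometry, a_c,
                             tunnel$depth_fraction * tot_c + h / UM_PER_MM)[1, ]
  that <- c(cos(a_c), -sin(a_c))
  uhat <- c(sin(a_c), cos(a_c))
  tgt <- cbind(f_center[1] + (mapped[, 1] * that[1] + mapped[, 2] * uhat[1]) /
                 UM_PER_MM,
               f_center[2] + (mapped[, 1] * that[2] + mapped[, 2] * uhat[2]) /
                 UM_PER_MM)
  ux <- tgt[, 1] - mesh$nodes[nodes, 1]
  uy <- tgt[, 2] - mesh$nodes[nodes, 2]
  boundary <- nodes %in% mesh$node_sets$tunnel_boundary
  contact <- mapped[, 3] > 0
  targets <- tibble::tibble(node = nodes, ux = ux, uy = uy,
                            boundary = boundary, contact = contact)
  sel <- boundary & contact
  rb <- rigid_body_constraint(
    nodes = nodes[sel],
    offsets = cbind(ux[sel], uy[sel]),
    center = point_at_depth(geometry, a_c, d_mid)[1, ],
    free = c(tx = FALSE, ty = TRUE, rot = FALSE))
  orphan <- !boundary & contact
  prescribed <- data.frame(
    node = rep(nodes[orphan], each = 2),
    dof = rep(c(1L, 2L), sum(orphan)),
    value = as.numeric(rbind(ux[orphan], uy[orphan])))
  list(targets = targets, rigid = rb, prescribed = prescribed,
       cross_section = cs)
}

#' Simulate ring implantation
#'
#' The three-stage pipeline: (1) pre-operative solve on the uncarved mesh
#' under IOP and layer pre-strain; (2) carve the tunnel and impose the ring
#' cross-section on its boundary, bound as a rigid outline; (3) release the
#' axial (y) translation of the rigid master and re-solve to equilibrium
#' under the same loads.  Both states are returned for differencing.
#'
#' @param geometry a [cornea_geometry()].
#' @param design a [ring_design()].
#' @param angle angular position along the ring arc, degrees.
#' @param mode `"axisymmetric"` or `"plane_strain"`.
#' @param tunnel a [tunnel_spec()].
#' @param density a [mesh_density()].
#' @param materials named list of [material_spec()].
#' @param prestrain a [prestrain_field()] (or `NULL` to disable).
#' @param iop_mmhg intraocular pressure, mmHg, applied to the posterior
#'   surface.
#' @param mesh optional pre-built uncarved mesh (bypasses `generate_mesh`).
#' @param preop optional pre-computed pre-operative `solution_field` for
#'   this mesh (re-used across angles).
#' @param stress_stiffening include the initial-stress geometric stiffness
#'   of the pre-strain in both solves (see [solve_static()]).
#' @return object of class `icrs_simulation` with `preop` and `postop`
#'   solution fields, the mesh and the imposition record.
#' @export
simulate_implantation <- function(geometry = cornea_geometry(),
                                  design = ring_design(),
                                  angle = 160,
                                  mode = c("axisymmetric", "plane_strain"),
                                  tunnel = tunnel_spec(),
                                  density = mesh_density(),
                                  materials = default_materials(),
                                  prestrain = prestrain_field(),
                                  iop_mmhg = 15,
                                  mesh = NULL, preop = NULL,
                                  stress_stiffening = TRUE) {
  mode <- match.arg(mode)
  if (is.null(mesh))
    mesh <- generate_mesh(geometry, tunnel, density, mode)
  p_kpa <- iop_mmhg * MMHG_TO_KPA
  base_load <- load_case(pressure = c(posterior_surface = p_kpa),
                         prestrain = prestrain)
  bc <- cornea_constraints(mesh)
  if (is.null(preop))
    preop <- solve_static(mesh, materials, base_load, bc,
                          stress_stiffening = stress_stiffening)
  carved <- carve_tunnel(mesh)
  cs <- ring_cross_section(design, angle)
  imp <- impose_ring(carved, cs, tunnel)
  post_load <- load_case(pressure = c(posterior_surface = p_kpa),
                         prestrain = prestrain,
                         prescribed = imp$prescribed)
  post_bc <- constraint_set(fixed = bc$fixed, rigid = list(imp$rigid))
  postop <- solve_static(carved, materials, post_load, post_bc,
                         stress_stiffening = stress_stiffening)
  structure(list(preop = preop, postop = postop, mesh = mesh,
                 carved = carved, imposition = imp, design = design,
                 angle = angle, mode = mode, geometry = mesh$geometry,
                 tunnel = tunnel),
            class = "icrs_simulation")
}

#' @export
print.icrs_simulation <- function(x, ...) {
  cat(sprintf(
    "<icrs_simulation> %s design at %g deg (%s): ring settle dy %.4g mm\n",
    x$design$name, x$angle, x$mode, x$postop$masters[[1]]["ty"]))
  invisible(x)
}
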