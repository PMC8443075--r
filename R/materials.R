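# Transversely isotropic layer materials in local (radial, circumferential)
# axes, plus the layer-wise pre-strain field.
#
# The local radial axis r runs through the thickness (along the surface
# normal); the plane of isotropy is spanned by the two circumferential
# directions: the in-plane tangent c and the out-of-plane direction z (hoop
# direction in the axisymmetric model, extrusion direction in plane strain).
# Voigt ordering used throughout: (rr, cc, zz, rc) with engineering shear.

#' Construct a layer material specification
#'
#' Transversely isotropic linear elasticity with the plane of isotropy
#' perpendicular to the through-thickness (radial) axis.  `nu_rc` is the
#' Poisson ratio giving circumferential contraction under radial load;
#' the reciprocal ratio `nu_cr = nu_rc * E_c / E_r` is derived from the
#' compliance symmetry requirement.  Thermodynamic admissibility (positive
#' definite stiffness) is checked at construction.
#'
#' @param E_r radial (through-thickness) modulus, kPa.
#' @param E_c circumferential (in-surface) modulus, kPa.
#' @param G_rc radial-circumferential shear modulus, kPa.
#' @param nu_cc Poisson ratio within the plane of isotropy.
#' @param nu_rc radial-circumferential Poisson ratio.
#' @param rho density, kg/m^3 (carried for bookkeeping; statics only).
#' @param label optional layer name.
#' @return object of class `material_spec`.
#' @examples
#' material_spec(E_r = 500, E_c = 1000, G_rc = 20, nu_cc = 0.34, nu_rc = 0.34)
#' isotropic_material(E = 0.1, nu = 0.4)  # epithelium
#' @export
material_spec <- function(E_r, E_c, G_rc, nu_cc, nu_rc, rho = 1062,
                          label = NULL) {
  stopifnot(E_r > 0, E_c > 0, G_rc > 0)
  spec <- structure(
    list(E_r = E_r, E_c = E_c, G_rc = G_rc,
         nu_cc = nu_cc, nu_rc = nu_rc,
         nu_cr = nu_rc * E_c / E_r,   # reciprocal relation
         rho = rho,
         isotropic = isTRUE(all.equal(E_r, E_c)) &&
           isTRUE(all.equal(nu_cc, nu_rc)) &&
           isTRUE(all.equal(G_rc, E_r / (2 * (1 + nu_rc)))),
         label = label),
    class = "material_spec")
  D <- tryCatch(stiffness_matrix(spec), error = function(e) e)
  if (inherits(D, "error")) stop(conditionMessage(D))
  spec
}

#' @rdname material_spec
#' @param E,nu isotropic modulus (kPa) and Poisson ratio.
#' @export
isotropic_material <- function(E, nu, rho = 1000, label = NULL) {
  material_spec(E_r = E, E_c = E, G_rc = E / (2 * (1 + nu)),
                nu_cc = nu, nu_rc = nu, rho = rho, label = label)
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf(
    "<material_spec%s> E_r %g kPa, E_c %g kPa, G_rc %g kPa, nu_cc %g, nu_rc %g\n",
    if (is.null(x$label)) "" else paste0(" ", x$label),
    x$E_r, x$E_c, x$G_rc, x$nu_cc, x$nu_rc))
  invisible(x)
}

#' Default corneal layer materials
#'
#' The three-layer material profile used throughout: an isotropic, very soft
#' epithelium (E = 0.1 kPa) and two transversely isotropic stromal layers, the
#' anterior one stiffer than the posterior, with circumferential (fiber)
#' stiffness exceeding radial (through-thickness) stiffness.
#'
#' @param posterior_nu_rc radial-circumferential Poisson ratio of the
#'   posterior stroma.  Default +0.34; a negative override is accepted for
#'   sensitivity checks.
#' @return named list of [material_spec()] objects with elements
#'   `epithelium`, `anterior_stroma`, `posterior_stroma`.
#' @export
default_materials <- function(posterior_nu_rc = 0.34) {
  list(
    epithelium = isotropic_material(E = 0.1, nu = 0.4, rho = 1000,
                                    label = "epithelium"),
    anterior_stroma = material_spec(E_r = 500, E_c = 1000, G_rc = 20,
                                    nu_cc = 0.34, nu_rc = 0.34, rho = 1062,
                                    label = "anterior_stroma"),
    posterior_stroma = material_spec(E_r = 400, E_c = 800, G_rc = 16,
                                     nu_cc = 0.34, nu_rc = posterior_nu_rc,
                                     rho = 1062, label = "posterior_stroma"))
}

#' Reduced compliance matrix of a layer material
#'
#' The 4x4 compliance in local axes and Voigt order (rr, cc, zz, rc) with
#' engineering shear.  In the axisymmetric mode the zz component is the hoop
#' direction; in plane strain it is the out-of-plane direction (condensed by
#' the kinematic constraint `eps_zz = 0` during assembly).  The matrix is the
#' same in both modes; only its kinematic use differs.
#'
#' @param spec a [material_spec()].
#' @param mode `"axisymmetric"` or `"plane_strain"` (recorded, not used).
#' @return 4x4 symmetric compliance matrix, 1/kPa.
#' @export
compliance_matrix <- function(spec, mode = c("axisymmetric", "plane_strain")) {
  mode <- match.arg(mode)
  with(spec, {
    S <- matrix(0, 4, 4)
    S[1, 1] <- 1 / E_r
    S[2, 2] <- S[3, 3] <- 1 / E_c
    S[1, 2] <- S[2, 1] <- S[1, 3] <- S[3, 1] <- -nu_rc / E_r
    S[2, 3] <- S[3, 2] <- -nu_cc / E_c
    S[4, 4] <- 1 / G_rc
    dimnames(S) <- rep(list(c("rr", "cc", "zz", "rc")), 2)
    S
  })
}

#' Reduced stiffness matrix (inverse compliance)
#'
#' @inheritParams compliance_matrix
#' @return 4x4 symmetric positive definite stiffness, kPa.  Errors with the
#'   offending eigenvalue if the spec is not thermodynamically admissible.
#' @export
stiffness_matrix <- function(spec, mode = c("axisymmetric", "plane_strain")) {
  S <- compliance_matrix(spec, mode)
  ev <- eigen(S[1:3, 1:3], symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "material not admissible: compliance eigenvalue %.3g <= 0", min(ev)))
  D <- solve(S)
  (D + t(D)) / 2
}

#' Local material axes at a point
#'
#' Rotation from global (x, y) axes to the local material axes: the radial
#' axis points along the surface normal (away from the anterior arc center),
#' the circumferential axis along the local tangent.  At the apex the radial
#' axis coincides with the apex axis (+y).
#'
#' @param point numeric length-2 `(x, y)` in mm.
#' @param geometry a [cornea_geometry()].
#' @return list with `angle` (rad, angle of the local radial axis from the
#'   global x-axis), `radial` and `circumferential` unit vectors.
#' @export
local_material_axes <- function(point, geometry) {
  center <- c(0, -geometry$r_anterior)
  v <- c(point[1] - center[1], point[2] - center[2])
  r <- v / sqrt(sum(v^2))
  list(angle = atan2(r[2], r[1]), radial = r,
       circumferential = c(r[2], -r[1]))
}

# Voigt strain transformation global -> local for local x'-axis direction
# (cs, sn) (unit).  Ordering (xx, yy, zz, xy)_global -> (rr, cc, zz, rc)_local
# with engineering shear.  zz is invariant under the in-plane rotation.
strain_rotation <- function(cs, sn) {
  matrix(c(cs^2,        sn^2,       0, cs * sn,
           sn^2,        cs^2,       0, -cs * sn,
           0,           0,          1, 0,
           -2 * cs * sn, 2 * cs * sn, 0, cs^2 - sn^2),
         4, 4, byrow = TRUE)
}

# rotate a local 4x4 stiffness into global axes: D_glob = t(Te) D_loc Te
rotate_stiffness <- function(D_loc, cs, sn) {
  Te <- strain_rotation(cs, sn)
  t(Te) %*% D_loc %*% Te
}

#' Layer-wise pre-strain field
#'
#' Initial strains representing the IOP-loaded reference state of the stroma:
#' compressive radial / tensile circumferential strain in the anterior
#' stroma, tensile in both directions in the posterior stroma, none in the
#' epithelium.  The circumferential value applies to both circumferential
#' directions (in-plane tangent and hoop/out-of-plane).
#'
#' @param anterior magnitude of the anterior stromal pre-strain (default
#'   0.015; radial component applied as `-anterior`).
#' @param posterior magnitude of the posterior stromal pre-strain (default
#'   0.010; both components positive).
#' @return tibble with columns `layer`, `eps_radial`, `eps_circumferential`.
#' @export
prestrain_field <- function(anterior = 0.015, posterior = 0.010) {
  tibble::tibble(
    layer = c("epithelium", "anterior_stroma", "posterior_stroma"),
    eps_radial = c(0, -anterior, posterior),
    eps_circumferential = c(0, anterior, posterior))
}

# local initial-strain Voigt vector (rr, cc, zz, rc) for a layer label
prestrain_vector <- function(field, layer) {
  if (is.null(field)) return(c(0, 0, 0, 0))
  i <- match(layer, field$layer)
  if (is.na(i)) stop(sprintf("unknown layer label '%s' in pre-strain field",
                             layer))
  c(field$eps_radial[i], field$eps_circumferential[i],
    field$eps_circumferential[i], 0)
}
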