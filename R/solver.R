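# Small-strain static FEM on quad-8 meshes: axisymmetric and plane-strain
# modes, transversely isotropic materials in local spherical axes, pressure
# and initial-strain (pre-strain) loads, Dirichlet and rigid-body multi-point
# constraints, sparse symmetric solve and stress recovery.
#
# Strain Voigt ordering (engineering shear): global (xx, yy, zz, xy), local
# (rr, cc, zz, rc).  In the axisymmetric mode x is the radial cylinder
# coordinate, zz the hoop component eps_hoop = u/x, and volume integrals
# carry the 2*pi*x weight; in plane strain zz is the suppressed out-of-plane
# component (B row identically zero) with unit depth.

# quad-8 serendipity shape functions and parent derivatives; node order:
# corners (-1,-1), (1,-1), (1,1), (-1,1) then midsides 5..8 between 1-2,
# 2-3, 3-4, 4-1
quad8_shape <- function(xi, eta) {
  N <- c(0.25 * (1 - xi) * (1 - eta) * (-xi - eta - 1),
         0.25 * (1 + xi) * (1 - eta) * (xi - eta - 1),
         0.25 * (1 + xi) * (1 + eta) * (xi + eta - 1),
         0.25 * (1 - xi) * (1 + eta) * (-xi + eta - 1),
         0.5 * (1 - xi^2) * (1 - eta),
         0.5 * (1 + xi) * (1 - eta^2),
         0.5 * (1 - xi^2) * (1 + eta),
         0.5 * (1 - xi) * (1 - eta^2))
  dN <- matrix(c(
    0.25 * (1 - eta) * (2 * xi + eta), 0.25 * (1 - xi) * (xi + 2 * eta),
    0.25 * (1 - eta) * (2 * xi - eta), 0.25 * (1 + xi) * (2 * eta - xi),
    0.25 * (1 + eta) * (2 * xi + eta), 0.25 * (1 + xi) * (xi + 2 * eta),
    0.25 * (1 + eta) * (2 * xi - eta), 0.25 * (1 - xi) * (2 * eta - xi),
    -xi * (1 - eta),                   -0.5 * (1 - xi^2),
    0.5 * (1 - eta^2),                 -eta * (1 + xi),
    -xi * (1 + eta),                   0.5 * (1 - xi^2),
    -0.5 * (1 - eta^2),                -eta * (1 - xi)),
    ncol = 2, byrow = TRUE)
  list(N = N, dN = dN)
}

# tensor-product Gauss rule on the parent square
gauss_2d <- function(n) {
  g1 <- switch(as.character(n),
               "2" = list(p = c(-1, 1) / sqrt(3), w = c(1, 1)),
               "3" = list(p = c(-sqrt(3 / 5), 0, sqrt(3 / 5)),
                          w = c(5, 8, 5) / 9),
               stop("unsupported rule"))
  pts <- as.matrix(expand.grid(xi = g1$p, eta = g1$p))
  w <- as.numeric(outer(g1$w, g1$w))
  list(pts = pts, w = w)
}

# cached shape evaluations at the 3x3 (stiffness) and 2x2 (recovery) rules
.quad8_cache <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      gp <- gauss_2d(n)
      gp$shape <- lapply(seq_along(gp$w), function(g)
        quad8_shape(gp$pts[g, 1], gp$pts[g, 2]))
      cache[[key]] <<- gp
    }
    cache[[key]]
  }
})

# direction cosines of the local radial axis at a point
material_axis_cs <- function(mesh, x, y) {
  ax <- mesh$material_axes
  if (is.null(ax)) ax <- list(type = "cartesian", angle = pi / 2)
  if (ax$type == "spherical") {
    v <- c(x - ax$center[1], y - ax$center[2])
    v / sqrt(sum(v^2))
  } else {
    c(cos(ax$angle), sin(ax$angle))
  }
}

# B matrix (4 x 16) at a Gauss point; returns also detJ, the physical point
# and shape values
b_matrix <- function(sh, xy, mode) {
  J <- t(sh$dN) %*% xy
  detJ <- det(J)
  dNxy <- sh$dN %*% t(solve(J))       # dN/dx, dN/dy
  p <- as.numeric(t(sh$N) %*% xy)
  B <- matrix(0, 4, 16)
  iu <- seq(1, 15, by = 2); iv <- iu + 1
  B[1, iu] <- dNxy[, 1]
  B[2, iv] <- dNxy[, 2]
  if (mode == "axisymmetric") B[3, iu] <- sh$N / p[1]
  B[4, iu] <- dNxy[, 2]
  B[4, iv] <- dNxy[, 1]
  list(B = B, detJ = detJ, point = p, N = sh$N)
}

# integration weight including the mode factor
mode_weight <- function(mode, x) if (mode == "axisymmetric") 2 * pi * x else 1

#' Element stiffness matrix
#'
#' Dense 16x16 stiffness of one quad-8 element with 3x3 Gauss integration.
#' The local material stiffness is rotated into global axes at every Gauss
#' point according to the mesh's material-axes convention.
#'
#' @param mesh a `cornea_mesh`.
#' @param element element index.
#' @param materials named list of [material_spec()] keyed by the mesh's
#'   material labels.
#' @param mode `"axisymmetric"` or `"plane_strain"` (defaults to the mesh
#'   mode).
#' @return 16x16 symmetric matrix (dof order u1, v1, ..., u8, v8).
#' @export
element_stiffness <- function(mesh, element, materials, mode = mesh$mode) {
  xy <- mesh$nodes[mesh$elements[element, ], ]
  D_loc <- stiffness_matrix(materials[[mesh$elem_material[element]]])
  gp <- .quad8_cache(3)
  Ke <- matrix(0, 16, 16)
  for (g in seq_along(gp$w)) {
    bm <- b_matrix(gp$shape[[g]], xy, mode)
    if (bm$detJ <= 0) stop("singular or inverted element Jacobian")
    cs <- material_axis_cs(mesh, bm$point[1], bm$point[2])
    D <- rotate_stiffness(D_loc, cs[1], cs[2])
    w <- gp$w[g] * bm$detJ * mode_weight(mode, bm$point[1])
    Ke <- Ke + w * (t(bm$B) %*% D %*% bm$B)
  }
  (Ke + t(Ke)) / 2
}

# Consistent nodal load from layer pre-strains over active elements.
# The pre-strain is a *stored* initial strain: the meshed geometry is the
# in-vivo (IOP-loaded) state and already carries the strain eps0, so the
# stress is sigma = D (eps + eps0) and the load contribution is
# -int B' D eps0 dV.  (A tensile circumferential pre-strain therefore
# produces tensile membrane stress, as in the loaded cornea.)
prestrain_load <- function(mesh, materials, field, mode = mesh$mode) {
  f <- numeric(2 * nrow(mesh$nodes))
  if (is.null(field)) return(f)
  gp <- .quad8_cache(3)
  for (e in which(mesh$active)) {
    lab <- mesh$elem_material[e]
    eps0 <- prestrain_vector(field, lab)
    if (all(eps0 == 0)) next
    xy <- mesh$nodes[mesh$elements[e, ], ]
    D_loc <- stiffness_matrix(materials[[lab]])
    sig0 <- D_loc %*% eps0
    fe <- numeric(16)
    for (g in seq_along(gp$w)) {
      bm <- b_matrix(gp$shape[[g]], xy, mode)
      cs <- material_axis_cs(mesh, bm$point[1], bm$point[2])
      Te <- strain_rotation(cs[1], cs[2])
      w <- gp$w[g] * bm$detJ * mode_weight(mode, bm$point[1])
      fe <- fe - w * as.numeric(t(bm$B) %*% t(Te) %*% sig0)
    }
    dofs <- as.integer(rbind(2 * mesh$elements[e, ] - 1,
                             2 * mesh$elements[e, ]))
    f[dofs] <- f[dofs] + fe
  }
  f
}

# consistent nodal load from a normal pressure (kPa, positive = pushing into
# the body) on an oriented boundary edge chain
pressure_load <- function(mesh, edge_set, p, mode = mesh$mode) {
  f <- numeric(2 * nrow(mesh$nodes))
  edges <- mesh$edge_sets[[edge_set]]
  if (is.null(edges)) stop(sprintf("unknown edge set '%s'", edge_set))
  g1 <- list(p = c(-sqrt(3 / 5), 0, sqrt(3 / 5)), w = c(5, 8, 5) / 9)
  for (k in seq_len(nrow(edges))) {
    nd <- edges[k, ]
    xy <- mesh$nodes[nd, ]
    for (g in seq_along(g1$p)) {
      xi <- g1$p[g]
      N <- c(0.5 * xi * (xi - 1), 1 - xi^2, 0.5 * xi * (xi + 1))
      dN <- c(xi - 0.5, -2 * xi, xi + 0.5)
      tng <- as.numeric(t(dN) %*% xy)          # d(position)/d(xi)
      pt <- as.numeric(t(N) %*% xy)
      n_out <- c(tng[2], -tng[1])              # CCW chain: outward normal
      traction <- -p * n_out                   # |n_out| = |tng| absorbs ds
      w <- g1$w[g] * mode_weight(mode, pt[1])
      for (a in 1:3) {
        f[2 * nd[a] - 1] <- f[2 * nd[a] - 1] + w * N[a] * traction[1]
        f[2 * nd[a]] <- f[2 * nd[a]] + w * N[a] * traction[2]
      }
    }
  }
  f
}

#' Define a load case
#'
#' @param pressure named numeric vector: pressure in kPa (positive pushes
#'   into the body) per boundary edge-set name, e.g.
#'   `c(posterior_surface = 15 * MMHG_TO_KPA)`.
#' @param prestrain a [prestrain_field()] tibble or `NULL`.
#' @param prescribed data frame with columns `node`, `dof` (1 = x, 2 = y),
#'   `value` (mm) of prescribed displacements, or `NULL`.
#' @return object of class `load_case`.
#' @export
load_case <- function(pressure = NULL, prestrain = NULL, prescribed = NULL) {
  structure(list(pressure = pressure, prestrain = prestrain,
                 prescribed = prescribed), class = "load_case")
}

#' Rigid-body multi-point constraint
#'
#' Ties every node of a set to a single master with 2D rigid kinematics
#' (two translations + one linearized rotation).  Each slave may carry a
#' fixed displacement offset (its imposed position on the rigid outline);
#' master components may be free (solved) or fixed at a prescribed value.
#' When the rotation is free, slave displacements are recomputed with the
#' exact finite rotation after the solve so that pairwise distances within
#' the set are preserved to machine precision.
#'
#' @param nodes integer node indices (>= 2, or 1 for a trivial tie).
#' @param offsets optional n x 2 matrix of slave displacement offsets (mm).
#' @param center reference point of the master, mm (default: centroid).
#' @param free logical length-3 `(tx, ty, rot)`: which master dofs are free.
#' @param master_values fixed values for non-free master dofs
#'   `(tx mm, ty mm, rot rad)`.
#' @return object of class `rigid_body`.
#' @export
rigid_body_constraint <- function(nodes, offsets = NULL, center = NULL,
                                  free = c(tx = FALSE, ty = TRUE,
                                           rot = FALSE),
                                  master_values = c(0, 0, 0)) {
  stopifnot(length(nodes) >= 1)
  if (is.null(offsets)) offsets <- matrix(0, length(nodes), 2)
  structure(list(nodes = as.integer(nodes), offsets = offsets,
                 center = center, free = as.logical(free),
                 master_values = master_values),
            class = "rigid_body")
}

#' Assemble a constraint set
#'
#' @param fixed data frame with columns `node`, `dof`, `value` of prescribed
#'   nodal displacements (use `value = 0` for supports).
#' @param rigid list of [rigid_body_constraint()] objects.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(fixed = NULL, rigid = list()) {
  if (is.null(fixed))
    fixed <- data.frame(node = integer(), dof = integer(), value = numeric())
  structure(list(fixed = fixed, rigid = rigid), class = "constraint_set")
}

# convenience: rows fixing the given dofs of a node set to zero
fix_nodes <- function(nodes, dofs = c(1, 2), value = 0) {
  expand <- expand.grid(node = nodes, dof = dofs)
  data.frame(node = expand$node, dof = expand$dof, value = value)
}

#' Default corneal boundary conditions
#'
#' Limbus pinned (both translations fixed; a 2D continuum node carries no
#' rotational dof, so pinning renders "fixed with the possibility to
#' rotate"), and, in the axisymmetric mode, zero radial displacement on the
#' apex-axis nodes (symmetry).
#'
#' @param mesh a `cornea_mesh`.
#' @return a [constraint_set()].
#' @export
cornea_constraints <- function(mesh) {
  fixed <- fix_nodes(mesh$node_sets$limbus, c(1, 2))
  if (mesh$mode == "axisymmetric")
    fixed <- rbind(fixed, fix_nodes(mesh$node_sets$apex_axis, 1))
  constraint_set(fixed = fixed)
}

# Initial-stress (geometric) element stiffness from the stored pre-stress
# sigma0 = D eps0: the linearization of equilibrium about the pre-tensioned
# reference state.  K_g[a,b] = int (grad Na . sigma grad Nb) I2 dV, plus the
# axisymmetric hoop term sigma_zz Na Nb / r^2 on the radial dofs.  A tensile
# membrane pre-stress stiffens transverse motion and transmits the
# arc-length changes imposed by the implant across the shell.
element_geometric_stiffness <- function(mesh, element, materials, field,
                                        mode = mesh$mode) {
  lab <- mesh$elem_material[element]
  eps0 <- prestrain_vector(field, lab)
  Kg <- matrix(0, 16, 16)
  if (all(eps0 == 0)) return(Kg)
  D_loc <- stiffness_matrix(materials[[lab]])
  sig0_loc <- as.numeric(D_loc %*% eps0)
  xy <- mesh$nodes[mesh$elements[element, ], ]
  gp <- .quad8_cache(3)
  iu <- seq(1, 15, by = 2); iv <- iu + 1
  for (g in seq_along(gp$w)) {
    sh <- gp$shape[[g]]
    J <- t(sh$dN) %*% xy
    detJ <- det(J)
    dNxy <- sh$dN %*% t(solve(J))
    p <- as.numeric(t(sh$N) %*% xy)
    cs <- material_axis_cs(mesh, p[1], p[2])
    Te <- strain_rotation(cs[1], cs[2])
    sig_g <- as.numeric(t(Te) %*% sig0_loc)   # (xx, yy, zz, xy) global
    Sg <- matrix(c(sig_g[1], sig_g[4], sig_g[4], sig_g[2]), 2, 2)
    core <- dNxy %*% Sg %*% t(dNxy)           # 8 x 8
    w <- gp$w[g] * detJ * mode_weight(mode, p[1])
    Kg[iu, iu] <- Kg[iu, iu] + w * core
    Kg[iv, iv] <- Kg[iv, iv] + w * core
    if (mode == "axisymmetric")
      Kg[iu, iu] <- Kg[iu, iu] +
        w * sig_g[3] * (sh$N %*% t(sh$N)) / p[1]^2
  }
  (Kg + t(Kg)) / 2
}

# assemble the global stiffness over active elements (sparse, symmetric);
# with `prestress` a prestrain field, the initial-stress geometric stiffness
# is included
assemble_stiffness <- function(mesh, materials, mode = mesh$mode,
                               prestress = NULL) {
  els <- which(mesh$active)
  nk <- length(els) * 256
  ii <- integer(nk); jj <- integer(nk); vv <- numeric(nk)
  pos <- 0L
  for (e in els) {
    Ke <- element_stiffness(mesh, e, materials, mode)
    if (!is.null(prestress))
      Ke <- Ke + element_geometric_stiffness(mesh, e, materials, prestress,
                                             mode)
    dofs <- as.integer(rbind(2 * mesh$elements[e, ] - 1,
                             2 * mesh$elements[e, ]))
    idx <- pos + seq_len(256)
    ii[idx] <- rep(dofs, times = 16)
    jj[idx] <- rep(dofs, each = 16)
    vv[idx] <- as.numeric(Ke)
    pos <- pos + 256L
  }
  n <- 2 * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

# build the affine constraint transformation u = u_p + T q
build_transformation <- function(mesh, constraints, loadcase) {
  n <- 2 * nrow(mesh$nodes)
  u_p <- numeric(n)
  kind <- integer(n)                  # 0 free, 1 prescribed, 2 rigid slave
  fixed <- constraints$fixed
  if (!is.null(loadcase$prescribed))
    fixed <- rbind(fixed, loadcase$prescribed)
  if (nrow(fixed)) {
    gdofs <- 2 * (fixed$node - 1) + fixed$dof
    kind[gdofs] <- 1L
    u_p[gdofs] <- fixed$value
  }
  # orphan nodes (attached to no active element) are pinned unless already
  # handled, so the system stays nonsingular
  used <- sort(unique(as.integer(mesh$elements[mesh$active, ])))
  orphan <- setdiff(seq_len(nrow(mesh$nodes)), used)
  if (length(orphan)) {
    od <- as.integer(rbind(2 * orphan - 1, 2 * orphan))
    kind[od[kind[od] == 0L]] <- 1L
  }
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  ncol_T <- 0L
  master_info <- list()
  for (b in seq_along(constraints$rigid)) {
    rb <- constraints$rigid[[b]]
    ctr <- rb$center %||% colMeans(mesh$nodes[rb$nodes, , drop = FALSE])
    udof <- 2 * rb$nodes - 1; vdof <- 2 * rb$nodes
    if (any(kind[c(udof, vdof)] != 0L))
      stop("rigid-body nodes overlap other constraints")
    kind[c(udof, vdof)] <- 2L
    px <- mesh$nodes[rb$nodes, 1] + rb$offsets[, 1]
    py <- mesh$nodes[rb$nodes, 2] + rb$offsets[, 2]
    u_p[udof] <- rb$offsets[, 1]
    u_p[vdof] <- rb$offsets[, 2]
    vals <- rb$master_values
    cols <- integer(3)
    # tx
    if (rb$free[1]) {
      ncol_T <- ncol_T + 1L; cols[1] <- ncol_T
      ti <- c(ti, udof); tj <- c(tj, rep(ncol_T, length(udof)))
      tv <- c(tv, rep(1, length(udof)))
    } else u_p[udof] <- u_p[udof] + vals[1]
    # ty
    if (rb$free[2]) {
      ncol_T <- ncol_T + 1L; cols[2] <- ncol_T
      ti <- c(ti, vdof); tj <- c(tj, rep(ncol_T, length(vdof)))
      tv <- c(tv, rep(1, length(vdof)))
    } else u_p[vdof] <- u_p[vdof] + vals[2]
    # rotation (linearized about the displaced position)
    if (rb$free[3]) {
      ncol_T <- ncol_T + 1L; cols[3] <- ncol_T
      ti <- c(ti, udof, vdof); tj <- c(tj, rep(ncol_T, 2 * length(udof)))
      tv <- c(tv, -(py - ctr[2]), px - ctr[1])
    } else if (vals[3] != 0) {
      u_p[udof] <- u_p[udof] - vals[3] * (py - ctr[2])
      u_p[vdof] <- u_p[vdof] + vals[3] * (px - ctr[1])
    }
    master_info[[b]] <- list(cols = cols, center = ctr, body = rb)
  }
  freed <- which(kind == 0L)
  col_of_free <- ncol_T + seq_along(freed)
  ti <- c(ti, freed); tj <- c(tj, col_of_free); tv <- c(tv, rep(1, length(freed)))
  ncol_T <- ncol_T + length(freed)
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n, ncol_T))
  list(T = T, u_p = u_p, masters = master_info, n_master_cols = ncol_T -
         length(freed))
}

#' Solve the static problem
#'
#' Assembles stiffness and loads over active elements, applies the constraint
#' set (Dirichlet + rigid-body) by transformation, solves the sparse
#' symmetric system and recovers stresses at 2x2 Gauss points in local
#' material axes.
#'
#' @param mesh a `cornea_mesh`.
#' @param materials named list of [material_spec()].
#' @param loadcase a [load_case()].
#' @param constraints a [constraint_set()].
#' @param mode solution mode, defaults to the mesh mode.
#' @param stress_stiffening include the initial-stress geometric stiffness
#'   of the stored pre-stress (linearization about the pre-tensioned
#'   reference state); ignored when the load case carries no pre-strain.
#' @return object of class `solution_field`: nodal displacements `u` (mm),
#'   per-element stress summary (kPa, local axes), per-element `von_mises`,
#'   deformed nodes, rigid-master results and the relative equilibrium
#'   residual.
#' @export
solve_static <- function(mesh, materials, loadcase, constraints,
                         mode = mesh$mode, stress_stiffening = TRUE) {
  K <- assemble_stiffness(mesh, materials, mode,
                          prestress = if (stress_stiffening)
                            loadcase$prestrain)
  f <- prestrain_load(mesh, materials, loadcase$prestrain, mode)
  for (nm in names(loadcase$pressure))
    f <- f + pressure_load(mesh, nm, loadcase$pressure[[nm]], mode)
  tr <- build_transformation(mesh, constraints, loadcase)
  A <- Matrix::forceSymmetric(Matrix::t(tr$T) %*% K %*% tr$T)
  b <- as.numeric(Matrix::t(tr$T) %*% (f - K %*% tr$u_p))
  q <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e)
                  stop("singular constrained system (unconstrained ",
                       "rigid-body modes?): ", conditionMessage(e)))
  u_vec <- tr$u_p + as.numeric(tr$T %*% q)
  masters <- list()
  for (b_i in seq_along(tr$masters)) {
    mi <- tr$masters[[b_i]]
    rb <- mi$body
    vals <- rb$master_values
    get <- function(k) if (mi$cols[k] > 0) q[mi$cols[k]] else vals[k]
    tx <- get(1); ty <- get(2); th <- get(3)
    masters[[b_i]] <- c(tx = tx, ty = ty, rot = th)
    if (rb$free[3] && abs(th) > 0) {
      # exact finite rotation so the set stays rigid to machine precision
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      P <- mesh$nodes[rb$nodes, , drop = FALSE] + rb$offsets
      ctr <- mi$center
      newp <- sweep((P - matrix(ctr, nrow(P), 2, byrow = TRUE)) %*% t(R), 2,
                    ctr + c(tx, ty), `+`)
      u_vec[2 * rb$nodes - 1] <- newp[, 1] - mesh$nodes[rb$nodes, 1]
      u_vec[2 * rb$nodes] <- newp[, 2] - mesh$nodes[rb$nodes, 2]
    }
  }
  resid <- as.numeric(Matrix::t(tr$T) %*% (K %*% u_vec - f))
  fnorm <- sqrt(sum((Matrix::t(tr$T) %*% f)^2))
  resid_rel <- sqrt(sum(resid^2)) / max(fnorm, 1e-30)
  u <- matrix(u_vec, ncol = 2, byrow = TRUE)
  st <- recover_stresses(mesh, materials, u_vec, loadcase$prestrain, mode)
  structure(
    list(u = u, deformed_nodes = mesh$nodes + u,
         stress = st$summary, gp_stress = st$gp,
         von_mises = st$summary$von_mises,
         masters = masters, residual_rel = resid_rel,
         mode = mode, mesh = mesh),
    class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(
    "<solution_field> %s, max |u| %.4g mm, equilibrium residual %.2e\n",
    x$mode, max(abs(x$u)), x$residual_rel))
  invisible(x)
}

# stress recovery at the 2x2 Gauss points, local material axes
recover_stresses <- function(mesh, materials, u_vec, prestrain, mode) {
  gp <- .quad8_cache(2)
  els <- which(mesh$active)
  ng <- length(gp$w)
  gp_sig <- array(NA_real_, c(nrow(mesh$elements), ng, 4),
                  dimnames = list(NULL, NULL, c("rr", "cc", "zz", "rc")))
  mean_sig <- matrix(NA_real_, nrow(mesh$elements), 4)
  vm_el <- rep(NA_real_, nrow(mesh$elements))
  for (e in els) {
    lab <- mesh$elem_material[e]
    D_loc <- stiffness_matrix(materials[[lab]])
    eps0 <- prestrain_vector(prestrain, lab)
    conn <- mesh$elements[e, ]
    xy <- mesh$nodes[conn, ]
    ue <- as.numeric(rbind(u_vec[2 * conn - 1], u_vec[2 * conn]))
    vms <- numeric(ng)
    for (g in seq_len(ng)) {
      bm <- b_matrix(gp$shape[[g]], xy, mode)
      cs <- material_axis_cs(mesh, bm$point[1], bm$point[2])
      Te <- strain_rotation(cs[1], cs[2])
      eps_loc <- as.numeric(Te %*% (bm$B %*% ue))
      sig <- as.numeric(D_loc %*% (eps_loc + eps0))
      gp_sig[e, g, ] <- sig
      vms[g] <- von_mises(sig)
    }
    mean_sig[e, ] <- colMeans(gp_sig[e, , , drop = FALSE][1, , ])
    vm_el[e] <- max(vms)
  }
  summary <- tibble::tibble(
    element = seq_len(nrow(mesh$elements)),
    material = mesh$elem_material,
    active = mesh$active,
    sigma_rr = mean_sig[, 1], sigma_cc = mean_sig[, 2],
    sigma_zz = mean_sig[, 3], sigma_rc = mean_sig[, 4],
    von_mises = vm_el)
  list(summary = summary, gp = gp_sig)
}

#' Von Mises equivalent stress
#'
#' Standard 3D von Mises stress from the four stress components carried by
#' the 2D models: `(sigma_rr, sigma_cc, sigma_zz, sigma_rc)`.
#'
#' @param sigma numeric length-4 vector or a matrix with 4 columns.
#' @return scalar (or vector) equivalent stress, same units as the input.
#' @export
von_mises <- function(sigma) {
  if (is.matrix(sigma))
    return(apply(sigma, 1, von_mises))
  s1 <- sigma[1]; s2 <- sigma[2]; s3 <- sigma[3]; t12 <- sigma[4]
  sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2) + 3 * t12^2)
}

#' Export nodal displacements as CSV
#'
#' @param solution a `solution_field`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_displacements_csv <- function(solution, path) {
  df <- tibble::tibble(node = seq_len(nrow(solution$u)),
                       x = solution$mesh$nodes[, 1],
                       y = solution$mesh$nodes[, 2],
                       ux = solution$u[, 1], uy = solution$u[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
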