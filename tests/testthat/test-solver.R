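fix_nodes <- corneafem:::fix_nodes

test_that("element stiffness annihilates rigid-body translations", {
  m <- mesh_rectangle(1, 1, 1, 1, x0 = 2)
  mat <- list(mat = material_spec(500, 1000, 20, 0.34, 0.34))
  Ke <- element_stiffness(m, 1, mat, mode = "plane_strain")
  expect_equal(Ke, t(Ke), tolerance = 1e-12)
  ux <- rep(c(1, 0), 8)
  uy <- rep(c(0, 1), 8)
  expect_lt(max(abs(Ke %*% ux)), 1e-9 * max(abs(Ke)))
  expect_lt(max(abs(Ke %*% uy)), 1e-9 * max(abs(Ke)))
})

test_that("uniform stretch reproduces the plane-strain Hooke closed form", {
  m <- mesh_rectangle(1, 1, 1, 1, x0 = 2)
  E <- 600; nu <- 0.25
  mat <- list(mat = isotropic_material(E, nu))
  alpha <- 1e-3
  u_vec <- as.numeric(t(cbind(alpha * m$nodes[, 1], 0)))
  st <- corneafem:::recover_stresses(m, mat, u_vec, NULL, "plane_strain")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  # local axes have r = y, c = x: global sxx is the "cc" slot
  expect_equal(unname(st$gp[1, , "cc"]), rep((lam + 2 * mu) * alpha, 4),
               tolerance = 1e-9)
  expect_equal(unname(st$gp[1, , "rr"]), rep(lam * alpha, 4),
               tolerance = 1e-9)
  expect_equal(unname(st$gp[1, , "zz"]), rep(lam * alpha, 4),
               tolerance = 1e-9)
})

test_that("patch test: uniform stress on a distorted anisotropic mesh", {
  mat <- list(mat = material_spec(500, 1000, 20, 0.34, 0.34))
  p <- 5
  # plane strain: uniaxial compression via edge pressure, rollers
  m <- mesh_rectangle(3, 3, 3, 2, x0 = 1, distort = 0.25)
  bc <- constraint_set(fixed = rbind(fix_nodes(m$node_sets$left, 1),
                                     fix_nodes(m$node_sets$bottom, 2)))
  sol <- solve_static(m, mat, load_case(pressure = c(right = p)), bc,
                      mode = "plane_strain")
  expect_lt(max(abs(sol$gp_stress[, , "cc"] + p)), 1e-9 * p)
  expect_lt(max(abs(sol$gp_stress[, , c("rr", "rc")])), 1e-9 * p)
  # axisymmetric: annulus under axial face pressure
  m2 <- mesh_rectangle(3, 2, 1, 1, x0 = 1.5, distort = 0.2)
  bc2 <- constraint_set(fixed = fix_nodes(m2$node_sets$bottom, 2))
  sol2 <- solve_static(m2, mat, load_case(pressure = c(top = p)), bc2,
                       mode = "axisymmetric")
  expect_lt(max(abs(sol2$gp_stress[, , "rr"] + p)), 1e-9 * p)
  expect_lt(max(abs(sol2$gp_stress[, , c("cc", "zz", "rc")])), 1e-9 * p)
})

test_that("axisymmetric ring under internal pressure matches Lame", {
  a <- 2; b <- 3; E <- 1000; nu <- 0.3; p <- 4
  m <- mesh_rectangle(8, 1, b - a, 0.4, x0 = a)
  iso <- list(mat = isotropic_material(E, nu))
  bc <- constraint_set(fixed = rbind(fix_nodes(m$node_sets$bottom, 2),
                                     fix_nodes(m$node_sets$top, 2)))
  sol <- solve_static(m, iso, load_case(pressure = c(left = p)), bc,
                      mode = "axisymmetric")
  r <- m$nodes[, 1]
  u_ref <- p * a^2 / (E * (b^2 - a^2)) * (1 + nu) *
    ((1 - 2 * nu) * r + b^2 / r)
  expect_lt(max(abs(sol$u[, 1] - u_ref)) / max(abs(u_ref)), 0.01)
})

test_that("thick sphere and thick cylinder match the Lame closed forms", {
  a <- 6; b <- 8; E <- 1000; nu <- 0.3; p <- 2
  sh <- mesh_shell(a, b, n_merid = 12, n_thick = 3)
  iso <- list(mat = isotropic_material(E, nu))
  bc <- constraint_set(fixed = rbind(fix_nodes(sh$node_sets$axis, 1),
                                     fix_nodes(sh$node_sets$equator, 2)))
  sol <- solve_static(sh, iso, load_case(pressure = c(inner = p)), bc)
  r <- sqrt(rowSums(sh$nodes^2))
  ur <- rowSums(sh$nodes * sol$u) / r
  ur_ref <- p * a^3 * r / (E * (b^3 - a^3)) *
    ((1 - 2 * nu) + (1 + nu) * b^3 / (2 * r^3))
  expect_lt(max(abs(ur - ur_ref)) / max(abs(ur_ref)), 0.01)
  # same mesh treated as a half-cylinder section in plane strain
  solc <- solve_static(sh, iso, load_case(pressure = c(inner = p)), bc,
                       mode = "plane_strain")
  urc <- rowSums(sh$nodes * solc$u) / r
  urc_ref <- p * a^2 / (E * (b^2 - a^2)) * (1 + nu) *
    ((1 - 2 * nu) * r + b^2 / r)
  expect_lt(max(abs(urc - urc_ref)) / max(abs(urc_ref)), 0.01)
})

test_that("zero loads give the zero solution with zero reactions", {
  mesh <- fx_mesh()
  sol <- solve_static(mesh, default_materials(), load_case(),
                      cornea_constraints(mesh))
  expect_equal(max(abs(sol$u)), 0)
  expect_true(all(is.na(sol$von_mises) | sol$von_mises < 1e-12))
})

test_that("the loaded cornea is in equilibrium with small pre-op motion", {
  pre <- fx_preop()
  expect_lt(pre$residual_rel, 1e-8)
  mesh <- fx_mesh()
  ids <- mesh$node_sets$apex_axis
  apex <- ids[which.min(mesh$node_depth[ids])]
  # the stored pre-strain nearly balances the IOP load: the imaged geometry
  # moves by well under a tenth of the corneal thickness
  expect_lt(abs(pre$u[apex, 2]), 0.055)
})

test_that("the solver is linear: doubling IOP doubles displacements", {
  mesh <- fx_mesh()
  bc <- cornea_constraints(mesh)
  s1 <- solve_static(mesh, default_materials(),
                     load_case(pressure = c(posterior_surface = 1)), bc)
  s2 <- solve_static(mesh, default_materials(),
                     load_case(pressure = c(posterior_surface = 2)), bc)
  expect_equal(2 * s1$u, s2$u, tolerance = 1e-9)
})

test_that("rigid bodies translate exactly and stay rigid under load", {
  m <- mesh_rectangle(4, 2, 2, 1, x0 = 1)
  iso <- list(mat = isotropic_material(500, 0.3))
  # prescribed master translation: every tied node displaces identically
  two <- m$node_sets$top[1:2]
  rb <- rigid_body_constraint(two, free = c(FALSE, FALSE, FALSE),
                              master_values = c(0.05, -0.02, 0))
  bc <- constraint_set(fixed = fix_nodes(m$node_sets$bottom, c(1, 2)),
                       rigid = list(rb))
  sol <- solve_static(m, iso, load_case(), bc, mode = "plane_strain")
  expect_equal(sol$u[two[1], ], c(0.05, -0.02), tolerance = 1e-12)
  expect_equal(sol$u[two[2], ], c(0.05, -0.02), tolerance = 1e-12)
  # free rigid body under pressure: pairwise distances preserved < 1e-9 mm
  set_nodes <- m$node_sets$top
  rb2 <- rigid_body_constraint(set_nodes, free = c(TRUE, TRUE, TRUE))
  bc2 <- constraint_set(fixed = fix_nodes(m$node_sets$bottom, c(1, 2)),
                        rigid = list(rb2))
  sol2 <- solve_static(m, iso, load_case(pressure = c(left = 3)), bc2,
                       mode = "plane_strain")
  xy <- m$nodes[set_nodes, ] + sol2$u[set_nodes, ]
  d_new <- as.numeric(dist(xy))
  d_old <- as.numeric(dist(m$nodes[set_nodes, ]))
  expect_lt(max(abs(d_new - d_old)), 1e-9)
  expect_gt(max(abs(sol2$u[set_nodes, ])), 0)  # it did move
})

test_that("von Mises follows the closed forms", {
  expect_equal(von_mises(c(7, 7, 7, 0)), 0)
  expect_equal(von_mises(c(13, 0, 0, 0)), 13)
  expect_equal(von_mises(c(0, 0, 0, 5)), sqrt(3) * 5)
  expect_equal(von_mises(rbind(c(7, 7, 7, 0), c(13, 0, 0, 0))), c(0, 13))
})

test_that("post-implantation stress localizes at the tunnel", {
  sim <- fx_sim("asymmetric", 80)
  post <- sim$postop
  act <- post$stress$active
  cx <- vapply(seq_len(nrow(sim$mesh$elements)), function(e)
    mean(sim$mesh$nodes[sim$mesh$elements[e, 1:4], 1]), numeric(1))
  vm <- post$von_mises
  peak <- which.max(ifelse(act, vm, -Inf))
  zone <- corneafem:::ring_zone_of(sim$tunnel)
  expect_gte(abs(cx[peak]), zone[1])
  expect_lte(abs(cx[peak]), zone[2])
  # central cornea carries a small fraction of the peak stress
  central <- act & abs(cx) < 1.5
  expect_lt(max(vm[central]), 0.3 * max(vm[act]))
})
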