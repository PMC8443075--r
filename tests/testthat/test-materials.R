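test_that("the isotropic limit reduces to the textbook compliance", {
  E <- 750; nu <- 0.3
  spec <- isotropic_material(E, nu)
  S <- compliance_matrix(spec)
  ref <- matrix(c(1, -nu, -nu, 0,
                  -nu, 1, -nu, 0,
                  -nu, -nu, 1, 0,
                  0, 0, 0, 2 * (1 + nu)), 4, 4, byrow = TRUE) / E
  expect_equal(unname(S), ref, tolerance = 1e-12)
})

test_that("stromal compliance entries follow the layer constants", {
  ant <- default_materials()$anterior_stroma
  S <- compliance_matrix(ant)
  expect_equal(S["rr", "rr"], 1 / 500)
  expect_equal(S["cc", "cc"], 1 / 1000)
  expect_equal(S["rc", "rc"], 1 / 20)
  expect_equal(S["rr", "cc"], -0.34 / 500)  # = -nu_cr / E_c by reciprocity
  expect_equal(S["cc", "zz"], -0.34 / 1000)
  expect_equal(S, t(S))
  # derived reciprocal ratio
  expect_equal(ant$nu_cr, 0.34 * 1000 / 500)
})

test_that("stiffness inverts compliance for every layer", {
  for (spec in default_materials()) {
    S <- compliance_matrix(spec)
    D <- stiffness_matrix(spec)
    expect_lt(max(abs(D %*% S - diag(4))), 1e-10)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
})

test_that("inadmissible constants are rejected with the eigenvalue", {
  expect_error(material_spec(E_r = 100, E_c = 1000, G_rc = 10,
                             nu_cc = 0.34, nu_rc = 0.9),
               "eigenvalue")
})

test_that("material axes rotate correctly and compose", {
  geo <- cornea_geometry()
  apex <- local_material_axes(c(0, 0), geo)
  expect_equal(apex$radial, c(0, 1), tolerance = 1e-12)
  ax30 <- local_material_axes(c(7.8 * sin(pi / 6),
                                7.8 * cos(pi / 6) - 7.8), geo)
  expect_equal(ax30$angle, pi / 2 - pi / 6, tolerance = 1e-12)
  # rotating by +30 deg and back returns the original stiffness
  D <- stiffness_matrix(default_materials()$anterior_stroma)
  cs <- cos(pi / 6); sn <- sin(pi / 6)
  D1 <- corneafem:::rotate_stiffness(D, cs, sn)
  D0 <- corneafem:::rotate_stiffness(D1, cs, -sn)
  expect_equal(unname(D0), unname(D), tolerance = 1e-9)
  # isotropic stiffness is rotation-invariant
  Di <- stiffness_matrix(isotropic_material(500, 0.3))
  expect_equal(corneafem:::rotate_stiffness(Di, cos(0.7), sin(0.7)),
               unname(Di), tolerance = 1e-9)
})

test_that("apex rotation swaps the in-plane normal components", {
  D <- stiffness_matrix(default_materials()$anterior_stroma)
  # at the apex the local radial axis is the global y-axis
  Dg <- corneafem:::rotate_stiffness(D, 0, 1)
  expect_equal(Dg[1, 1], D[2, 2], tolerance = 1e-12)  # global xx <- local cc
  expect_equal(Dg[2, 2], D[1, 1], tolerance = 1e-12)  # global yy <- local rr
  expect_equal(Dg[3, 3], D[3, 3], tolerance = 1e-12)
})

test_that("pre-strain field carries the layer-wise signs", {
  ps <- prestrain_field()
  expect_equal(ps$eps_radial[ps$layer == "anterior_stroma"], -0.015)
  expect_equal(ps$eps_circumferential[ps$layer == "anterior_stroma"], 0.015)
  expect_equal(ps$eps_radial[ps$layer == "posterior_stroma"], 0.010)
  expect_equal(ps$eps_radial[ps$layer == "epithelium"], 0)
  expect_error(corneafem:::prestrain_vector(ps, "bowman"), "unknown layer")
})

test_that("zero pre-strain contributes no load", {
  mesh <- fx_mesh()
  f <- corneafem:::prestrain_load(mesh, default_materials(),
                                  prestrain_field(0, 0))
  expect_equal(max(abs(f)), 0)
})

test_that("uniform stored pre-strain on a free body relaxes stress-free", {
  # axisymmetric annular block, restrained only against axial translation:
  # the body contracts uniformly by the stored strain (u = -eps * x radially)
  # and ends with numerically zero residual stress
  m <- mesh_rectangle(2, 2, 1, 1, x0 = 3)
  mat <- list(mat = isotropic_material(400, 0.3))
  eps <- 0.01
  ps <- tibble::tibble(layer = "mat", eps_radial = eps,
                       eps_circumferential = eps)
  fixed <- data.frame(node = m$node_sets$left[1], dof = 2, value = 0)
  sol <- solve_static(m, mat, load_case(prestrain = ps),
                      constraint_set(fixed = fixed), mode = "axisymmetric",
                      stress_stiffening = FALSE)
  expect_lt(max(abs(sol$gp_stress), na.rm = TRUE), 1e-7)
  expect_equal(sol$u[, 1], -eps * m$nodes[, 1], tolerance = 1e-9)
})

test_that("the loaded cornea shows the two-layer stress pattern", {
  pre <- fx_preop()
  st <- pre$stress
  mean_cc <- function(l) mean(st$sigma_cc[st$material == l & st$active])
  # tensile membrane stress, anterior stiffer layer carrying more
  expect_gt(mean_cc("anterior_stroma"), mean_cc("posterior_stroma"))
  expect_gt(mean_cc("posterior_stroma"), 0)
  # through-thickness stress is small and compressive on average
  expect_lt(abs(mean(st$sigma_rr[st$material == "anterior_stroma" &
                                   st$active])), 1)
  # total radial strain (compliance oracle on the mean layer stress) is
  # negative anteriorly: Poisson thinning under biaxial tension dominates
  S <- compliance_matrix(default_materials()$anterior_stroma)
  sig <- c(mean(st$sigma_rr[st$material == "anterior_stroma" & st$active]),
           mean_cc("anterior_stroma"),
           mean(st$sigma_zz[st$material == "anterior_stroma" & st$active]),
           0)
  expect_lt((S %*% sig)[1], 0)
})
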