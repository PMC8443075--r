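test_that("ring cross-sections interpolate linearly along the arc", {
  d <- ring_design()
  cs0 <- ring_cross_section(d, 0)
  expect_equal(cs0$thickness, 150)
  expect_equal(cs0$base, 600)
  cs1 <- ring_cross_section(d, 160)
  expect_equal(cs1$thickness, 300)
  expect_equal(cs1$base, 800)
  cs_mid <- ring_cross_section(d, 80)
  expect_equal(cs_mid$thickness, 225)
  expect_equal(cs_mid$base, 700)
  expect_error(ring_cross_section(d, 200), "outside")
  # triangle outline closes with area base * thickness / 2
  o <- cs1$outline
  expect_equal(o[1, ], o[nrow(o), ])
  area <- abs(sum(o[-nrow(o), 1] * o[-1, 2] - o[-1, 1] * o[-nrow(o), 2])) / 2
  expect_equal(area, 800 * 300 / 2)
})

test_that("study presets fix the non-varied parameter", {
  sd <- study_designs()
  expect_equal(ring_cross_section(sd$thickness_only, 100)$base, 700)
  expect_equal(ring_cross_section(sd$base_only, 100)$thickness, 225)
  expect_equal(ring_cross_section(sd$symmetric, 37)$thickness, 225)
  expect_equal(ring_cross_section(sd$symmetric, 37)$base, 600)
})

test_that("imposition requires a carved mesh and maps the full opening", {
  mesh <- fx_mesh()
  cs <- ring_cross_section(ring_design(), 160)
  expect_error(impose_ring(mesh, cs, mesh$tunnel), "carved")
  carved <- carve_tunnel(mesh)
  imp <- impose_ring(carved, cs, mesh$tunnel)
  # the 30-um void opens to the 300-um ring thickness
  tgt_y <- mesh$nodes[imp$targets$node, 2] + imp$targets$uy
  opening <- diff(range(tgt_y[imp$targets$contact]))
  expect_gt(opening, 0.29)  # ~ triangle height, tilted by the local slope
})

test_that("the imposed outline area matches the triangle area", {
  carved <- carve_tunnel(fx_mesh())
  for (ang in c(0, 160)) {
    cs <- ring_cross_section(ring_design(), ang)
    imp <- impose_ring(carved, cs, carved$tunnel)
    tg <- imp$targets[imp$targets$boundary & imp$targets$contact, ]
    xy <- cbind(carved$nodes[tg$node, 1] + tg$ux,
                carved$nodes[tg$node, 2] + tg$uy)
    # order the outline points by angle around the centroid (shoelace)
    ctr <- colMeans(xy)
    ord <- order(atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1]))
    p <- xy[ord, ]
    area <- abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                      c(p[-1, 1], p[1, 1]) * p[, 2])) / 2
    area_um2 <- area * 1e6
    expect_lt(abs(area_um2 - cs$base * cs$thickness / 2) /
                (cs$base * cs$thickness / 2), 0.02)
  }
})

test_that("inner-edge expansion absorbs a base wider than the tunnel", {
  m <- corneafem:::triangle_map(xi = c(-400, 0, 400), eta = c(0, 0, 0),
                                w = 800, h = 30, b = 1000, th = 200)
  # outer edge unchanged, inner edge stretched inward by the overhang
  expect_equal(unname(m[3, "xi"]), 400)
  expect_equal(unname(m[1, "xi"]), -600)
  expect_equal(unname(m[2, "xi"]), 0)
  # without overhang the tangential station is preserved
  m0 <- corneafem:::triangle_map(xi = c(-400, 137, 400), eta = rep(15, 3),
                                 w = 800, h = 30, b = 600, th = 200)
  expect_equal(unname(m0[, "xi"]), c(-400, 137, 400))
  expect_equal(unname(m0[1, "contact"]), 0)  # beyond the 600-um base
  expect_equal(unname(m0[2, "contact"]), 1)
})

test_that("a vanishing implant leaves the cornea essentially unchanged", {
  sim <- simulate_implantation(
    design = ring_design(thickness = c(1, 1), base = c(800, 800)),
    angle = 80, mesh = fx_mesh(), preop = fx_preop())
  ca <- curvature_analysis(sim)
  real <- fx_analysis("asymmetric", 160)
  # closing the 30-um tunnel void registers only a small local blip, far
  # below any real design, and next to nothing in the central zone
  expect_lt(max(abs(ca$delta$delta)),
            0.25 * max(abs(real$delta$delta)))
  expect_lt(abs(ca$summary$central_delta), 1)
})

test_that("implantation flattens peripherally above the ring", {
  ca <- fx_analysis("asymmetric", 160)
  expect_lt(ca$summary$peripheral_delta, -10)
  zone <- corneafem:::ring_zone_of(tunnel_spec())
  expect_gte(abs(ca$summary$peripheral_x), zone[1])
  expect_lte(abs(ca$summary$peripheral_x), zone[2])
  # steepening outside the ring zone, as the shell rises over the implant
  expect_gt(ca$summary$steepening_max, 0)
})

test_that("the ring outline stays rigid in the post-operative state", {
  sim <- fx_sim("asymmetric", 160)
  rb <- sim$imposition$rigid
  xy <- sim$mesh$nodes[rb$nodes, ] + sim$postop$u[rb$nodes, ]
  target <- sim$mesh$nodes[rb$nodes, ] + rb$offsets
  d_new <- as.numeric(dist(xy))
  d_tgt <- as.numeric(dist(target))
  expect_lt(max(abs(d_new - d_tgt)), 1e-9)
  # the ring settled axially but kept its radial station
  expect_equal(sim$postop$masters[[1]][["tx"]], 0)
  expect_gt(abs(sim$postop$masters[[1]][["ty"]]), 0)
})

test_that("plane strain gives a one-sided response", {
  ca <- fx_analysis("asymmetric", 160, "plane_strain")
  d <- ca$delta
  implanted <- abs(d$delta[d$x > 1.6 & d$x < 4.4])
  contralateral <- abs(d$delta[d$x < -1.6 & d$x > -4.4])
  expect_gt(max(implanted), 5 * max(contralateral))
})
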