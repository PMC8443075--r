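# Shared fixtures: all geometry/mesh/solution objects are built in code and
# memoized across test files (the implantation pipeline is deterministic).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

fx_geometry <- function() memo("geometry", cornea_geometry())

fx_mesh <- function(mode = "axisymmetric") {
  memo(paste0("mesh_", mode),
       generate_mesh(fx_geometry(), tunnel_spec(), mesh_density(), mode))
}

fx_load <- function() {
  load_case(pressure = c(posterior_surface = 15 * MMHG_TO_KPA),
            prestrain = prestrain_field())
}

fx_preop <- function(mode = "axisymmetric") {
  memo(paste0("preop_", mode), {
    mesh <- fx_mesh(mode)
    solve_static(mesh, default_materials(), fx_load(),
                 cornea_constraints(mesh))
  })
}

fx_sim <- function(design_name, angle, mode = "axisymmetric") {
  key <- paste("sim", design_name, angle, mode, sep = "_")
  memo(key, simulate_implantation(
    design = study_designs()[[design_name]], angle = angle, mode = mode,
    mesh = fx_mesh(mode), preop = fx_preop(mode)))
}

fx_analysis <- function(design_name, angle, mode = "axisymmetric") {
  key <- paste("ca", design_name, angle, mode, sep = "_")
  memo(key, curvature_analysis(fx_sim(design_name, angle, mode)))
}

fx_study <- function() memo("study", run_study())

# analytic circular profile (anterior-like dome, apex at y = 0)
circle_profile <- function(R, xmax = 5.8, n = 129, two_sided = FALSE) {
  x <- seq(if (two_sided) -xmax else 0, xmax, length.out = n)
  tibble::tibble(x = x, y = sqrt(R^2 - x^2) - R)
}
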