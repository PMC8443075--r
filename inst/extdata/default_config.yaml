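# Default simulation configuration: every value here mirrors the package
# defaults, so an empty config gives the same model.  Units: mm for radii
# and chord, um for thicknesses, degrees for arcs, kPa for moduli.
geometry:
  r_anterior: 7.8          # anterior surface radius
  r_posterior: 6.4         # posterior surface radius
  cct: 550                 # central corneal thickness (450 = thin variant)
  t_epi: 50                # epithelium thickness
  f_anterior_stroma: 0.4   # anterior share of the stromal thickness
  half_chord: 5.8          # corneal half-width at the limbus
tunnel:
  width: 800
  height: 30
  depth_fraction: 0.70
  center_radial_position: 3.0
design:
  arc_length: 160
  thickness: [150, 300]
  base: [600, 800]
loads:
  iop_mmhg: 15
  prestrain_anterior: 0.015
  prestrain_posterior: 0.010
materials:
  epithelium:      {E: 0.1, nu: 0.4, rho: 1000}
  anterior_stroma: {E_r: 500, E_c: 1000, G_rc: 20, nu_cc: 0.34, nu_rc: 0.34,
                    rho: 1062}
  posterior_stroma: {E_r: 400, E_c: 800, G_rc: 16, nu_cc: 0.34, nu_rc: 0.34,
                     rho: 1062}
curvature:
  n_index: 1.3375
  grid_spacing_mm: 0.025
  bfs_zone_mm: 10
  central_zone_mm: 4
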