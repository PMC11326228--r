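# Shared desk-scale fixtures for solver tests.

# small two-layer grid (1.5 mm x (60 + 300) um)
small_two_layer <- function(dx_um = 25, dy_um = 15) {
  geo <- cochlear_geometry(length_mm = 1.5, corti_height_um = 60,
                           scala_height_um = 300, dx_um = dx_um)
  flow_grid(geo, dy_um = dy_um)
}

small_wave <- function(a_peak_um = 1, type = "traveling") {
  synth_wall_motion(a_peak_um = a_peak_um, f_hz = 1000, x_peak_mm = 1.05,
                    domain_mm = 1.5, type = type,
                    peak_width_mm = 0.25, stall_margin_mm = 0.3,
                    c_base_mm_s = 8000, c_peak_mm_s = 400)
}

run_small <- function(wave, grid = small_two_layer(), K = 1,
                      tol = 1e-4, n_max = 25) {
  pr <- flow_problem(grid, wall = wave, membrane = membrane_model(K),
                     dt_s = 1e-5)
  run_periodic(pr, solver_config(n_cycles_max = n_max, tol_periodic = tol))
}

# hand-built response curve tibble for effect_time() unit tests
make_curve <- function(y, dt_min = 1, channel = 1L) {
  n <- length(y)
  tibble::tibble(channel = channel, sequence = seq_len(n),
                 t_min = seq(-2, by = dt_min, length.out = n),
                 driven = y, normalized = y, baseline = 1)
}
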