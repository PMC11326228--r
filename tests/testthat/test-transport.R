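test_that("uniform concentration in a sealed domain is a fixed point and mass is conserved", {
  g <- channel_grid(0.5, 100, dx_um = 25, dy_um = 20)
  cfg <- transport_config(patch = "scala_bottom", patch_extent_mm = 0)
  no_patch <- matrix(FALSE, g$nx, g$ny)
  C <- matrix(3.7, g$nx, g$ny)
  C2 <- advance_concentration(C, g, cfg, dt_s = 1, patch = no_patch)
  expect_equal(max(abs(C2 - 3.7)), 0, tolerance = 1e-12)
  # non-uniform field: total mass conserved with sealed walls
  C <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  m0 <- sum(C)
  for (k in 1:50) C <- advance_concentration(C, g, cfg, dt_s = 5, patch = no_patch)
  expect_lt(abs(sum(C) / m0 - 1), 1e-10)
})

test_that("the advective CFL guard names the violation", {
  g <- small_two_layer()
  sol <- run_small(small_wave(4))
  cfg <- transport_config()
  C <- matrix(0, g$nx, g$ny)
  expect_error(
    advance_concentration(C, g, cfg, dt_s = 1e7, drift = sol),
    "CFL")
})

test_that("pure diffusion from a fixed plane matches the erfc solution", {
  g <- channel_grid(2, 100, dx_um = 20, dy_um = 20)
  cfg <- transport_config(patch = "basal_wall", horizon_min = 4)
  run <- run_delivery(g, cfg)
  D <- cfg$D
  t_end <- max(run$times_s)
  x_src <- g$x_c[1]                       # Dirichlet plane (pinned cell centre)
  xr <- g$x_c - x_src
  # C0 * erfc(x / (2 sqrt(D t))), with erfc(z) = 2 pnorm(-sqrt(2) z)
  z <- xr / (2 * sqrt(D * t_end))
  C_ex <- cfg$C0 * 2 * stats::pnorm(-sqrt(2) * z)
  C_num <- run$final[, 3]
  sel <- xr > 0
  err <- sqrt(mean((C_num[sel] - C_ex[sel])^2)) / sqrt(mean(C_ex[sel]^2))
  expect_lt(err, 0.02)
  expect_lt(run$budget_rel_err, 1e-3)
  expect_gte(run$c_min, -1e-6 * cfg$C0)
  expect_lte(run$c_max, cfg$C0 * (1 + 1e-6))
})

test_that("the silence-case effect-time front advances monotonically", {
  g <- channel_grid(2, 100, dx_um = 20, dy_um = 20)
  cfg <- transport_config(patch = "basal_wall", horizon_min = 4)
  run <- run_delivery(g, cfg)
  em <- effect_time_map(run)
  reached <- em[em$reached, ]
  expect_gt(nrow(reached), 20)
  expect_true(all(diff(reached$t_e_min) > 0))
})

test_that("a zero drift field reproduces the pure-diffusion run exactly", {
  g <- small_two_layer()
  cfg <- transport_config(horizon_min = 2)
  still <- run_small(small_wave(0), n_max = 6, tol = 1e-3)
  expect_equal(max(abs(still$u_drift)), 0)
  r0 <- run_delivery(g, cfg, drift = NULL)
  r1 <- run_delivery(g, cfg, drift = still)
  expect_identical(r0$line, r1$line)
})

test_that("effect times interpolate crossings and flag unreached points", {
  cfg <- transport_config()
  thr <- cfg$f_thr * cfg$C0
  t1 <- 500
  hist <- tidyr::expand_grid(time_s = seq(0, t1, by = 50), x_mm = c(0.5, 1))
  hist$conc_mM <- ifelse(hist$x_mm == 0.5, cfg$C0 * hist$time_s / t1, 0)
  em <- effect_time_map(hist, cfg)
  expect_equal(em$t_e_min[em$x_mm == 0.5], cfg$f_thr * t1 / 60, tolerance = 1e-12)
  expect_false(em$reached[em$x_mm == 1])
  expect_true(is.na(em$t_e_min[em$x_mm == 1]))
  # point inside the fixed patch crosses at time zero
  hist2 <- tidyr::expand_grid(time_s = c(0, 100), x_mm = 0.1)
  hist2$conc_mM <- cfg$C0
  expect_equal(effect_time_map(hist2, cfg)$t_e_min, 0)
  expect_error(effect_time_map(hist2[0, ], cfg), "empty")
})
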