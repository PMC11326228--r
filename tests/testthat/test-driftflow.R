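test_that("Darcy membrane law follows its sign convention and limits", {
  expect_equal(membrane_velocity(0, 0, K = 1)$u_p, 0)
  expect_equal(membrane_velocity(2, 0, K = 1)$u_p, -2)
  expect_equal(membrane_velocity(5, 1, K = 0, u_m = 0.3)$u_f, 0.3)
  expect_error(membrane_model(-1), "non-negative")
})

test_that("quiescent fluid with rigid walls stays exactly at rest", {
  g <- small_two_layer()
  pr <- flow_problem(g, wall = NULL, dt_s = 1e-5)
  st <- advance_flow(pr, NULL, n_steps = 20)
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
  expect_equal(max(abs(st$p)), 0)
})

test_that("pressure-driven channel flow converges to the Poiseuille profile at second order", {
  nu <- 70e-6; h <- 100e-6; fx <- 1e-3
  err <- vapply(c(10, 5), function(dy) {
    g <- channel_grid(0.2, 100, dx_um = 50, dy_um = dy, periodic = TRUE)
    pr <- flow_problem(g, wall = NULL, dt_s = 2e-5, fx_m_s2 = fx)
    st <- advance_flow(pr, NULL, n_steps = 300)
    u_ex <- fx / (2 * nu) * g$y_c * (h - g$y_c)
    sqrt(mean((st$u[2, ] - u_ex)^2)) / sqrt(mean(u_ex^2))
  }, numeric(1))
  expect_lt(err[2], 0.01)
  order <- log2(err[1] / err[2])
  expect_gt(order, 1.7); expect_lt(order, 2.3)
})

test_that("oscillating-plate flow reproduces the Stokes boundary layer within 2%", {
  nu <- 70e-6; f <- 1000; om <- 2 * pi * f; U0 <- 1e-3
  delta <- sqrt(2 * nu / om)
  g <- channel_grid(0.2, 1000, dx_um = 50, dy_um = 12.5, periodic = TRUE)
  pr <- flow_problem(g, wall = NULL, dt_s = 1e-5,
                     ub_fun = function(x, t) rep(U0 * cos(om * t), length(x)))
  st <- advance_flow(pr, NULL, n_steps = 100 * 12)
  y <- g$y_c
  sel <- y < 4 * delta
  u_ex <- U0 * exp(-y / delta) * cos(om * st$t - y / delta)
  err <- sqrt(mean((st$u[2, sel] - u_ex[sel])^2)) /
    sqrt(mean((U0 * exp(-y[sel] / delta))^2))
  expect_lt(err, 0.02)
})

test_that("period averaging cancels oscillatory histories and validates its inputs", {
  ts <- seq(0, 1, length.out = 65)
  hist <- lapply(ts, function(t) matrix(3.2 * sin(2 * pi * t), 2, 2))
  avg <- drift_velocity(hist, period_s = 1)
  expect_lt(max(abs(avg)), 1e-12)
  expect_error(drift_velocity(hist[1:2], period_s = 1), "3 samples")
  expect_error(drift_velocity(hist), "period_s")
})

test_that("a small-amplitude wall-driven flow reaches its periodic state within 10 cycles", {
  sol <- run_small(small_wave(0.05), tol = 1e-3)
  expect_true(sol$converged)
  expect_lte(sol$n_cycles, 10)
  expect_lte(sol$periodicity, 1e-3)
  g <- sol$grid
  u_scale <- max(abs(sol$state$u), abs(sol$state$v))
  expect_lt(sol$div_norm_max, 1e-8 * u_scale / g$dx)
})

test_that("drift is insensitive to the membrane permeability over an order of magnitude", {
  m1 <- max(abs(run_small(small_wave(1), K = 0.3)$u_drift))
  m2 <- max(abs(run_small(small_wave(1), K = 3)$u_drift))
  expect_lt(abs(m2 / m1 - 1), 0.2)
})

test_that("tidy and glance expose the drift field with layer labels", {
  sol <- run_small(small_wave(1))
  td <- tidy(sol)
  expect_setequal(unique(td$layer), c("scala", "corti"))
  expect_equal(nrow(td), sol$grid$nx * sol$grid$ny)
  gl <- glance(sol)
  expect_true(gl$converged)
  expect_gt(gl$max_drift_um_s, 0)
})
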