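geo <- cochlear_geometry()
wv <- traveling_wave(4.5, geo)

test_that("envelope peaks at the CF place, vanishes apical of the stall point, and scales linearly with gain", {
  x <- seq(0, 12, by = 0.01)
  A <- amplitude_envelope(wv, x)
  expect_true(all(A >= 0))
  expect_equal(x[which.max(A)], wv$x_peak_mm, tolerance = 0.01)
  expect_true(all(A[x >= wv$x_stall_mm] == 0))
  expect_equal(amplitude_envelope(wv, wv$x_peak_mm), wv$a_peak_um,
               tolerance = 1e-12)
  wv_g <- traveling_wave(4.5, geo, active_gain = 0.1)
  expect_equal(amplitude_envelope(wv_g, x), 0.1 * A, tolerance = 1e-12)
  expect_error(
    traveling_wave(4.5, cochlear_geometry(length_mm = 3),
                   map = place_frequency_map()),
    "outside")
})

test_that("phase lag accumulates apically with decaying phase velocity", {
  x <- seq(0, 12, length.out = 2001)
  phi <- phase_profile(wv, x)
  expect_true(all(diff(phi) < 0))
  prof <- wave_profile(wv, x)
  expect_gt(prof$c_mm_per_s[1], prof$c_mm_per_s[which.min(abs(x - wv$x_peak_mm))])
  # -d(phi)/dx reconstructs k(x) within 1% on the smooth interior
  k_fd <- -diff(phi) / diff(x)
  k_mid <- wv$k_fun((x[-1] + x[-length(x)]) / 2)
  interior <- x[-1] > 0.5 & x[-1] < 11.5
  expect_lt(max(abs(k_fd[interior] / k_mid[interior] - 1)), 0.01)
})

test_that("constant-velocity profile gives a linear phase", {
  w <- synth_wall_motion(c_base_mm_s = 2000, c_peak_mm_s = 2000)
  x <- seq(0, 3, length.out = 100)
  phi <- phase_profile(w, x)
  expect_equal(phi, -2 * pi * 1000 / 2000 * x, tolerance = 1e-6)
})

test_that("wall motion is periodic with zero per-period mean and vanishes at zero amplitude", {
  x <- seq(0, 12, by = 0.1)
  t1 <- 1.23e-3
  s1 <- wall_motion(wv, x, t1)
  s2 <- wall_motion(wv, x, t1 + wv$period_s)
  expect_equal(s1$displacement_um, s2$displacement_um, tolerance = 1e-9)
  # uniform sampling of a pure sinusoid over one period averages to zero
  N <- 64
  disp <- vapply(seq_len(N) - 1, function(k) {
    wall_motion(wv, x, k * wv$period_s / N)$displacement_um
  }, numeric(length(x)))
  expect_lt(max(abs(rowMeans(disp))), 1e-12 * wv$a_peak_um)
  w0 <- traveling_wave(4.5, geo, active_gain = 0)
  expect_true(all(wall_motion(w0, x, t1)$displacement_um == 0))
})
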