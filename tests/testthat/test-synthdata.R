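test_that("the generator is byte-identical under a fixed seed and leaves the caller's RNG alone", {
  cfg <- synth_config(seed = 11, n_sequences = 3, n_baseline_seq = 1,
                      t_e_min = c(0.4, 0.7, 1))
  set.seed(99); before <- rnorm(1)
  a <- synth_recording(cfg)
  b <- synth_recording(cfg)
  expect_identical(a$recording$waveform, b$recording$waveform)
  expect_identical(a$truth, b$truth)
  set.seed(99)
  expect_identical(rnorm(1), before)
  d1 <- synth_effect_time_dataset(seed = 5)
  d2 <- synth_effect_time_dataset(seed = 5)
  expect_identical(d1, d2)
})

test_that("generated recordings satisfy the schedule contract of the analysis stage", {
  cfg <- synth_config(seed = 2, n_sequences = 3, n_baseline_seq = 1,
                      t_e_min = c(0.4, 0.7, 1))
  syn <- synth_recording(cfg)
  seg <- segment_responses(syn$recording)
  expect_equal(nrow(seg), 3 * 52 * 3)  # sequences x segments x channels
  expect_equal(nrow(syn$recording$waveform) / syn$recording$fs_hz, 3 * 57.2,
               tolerance = 1e-6)
})

test_that("effect-time datasets sit exactly on the trend without scatter and centre correctly with it", {
  a0 <- 2.2
  d0 <- synth_effect_time_dataset(n = 20, a0_min_mm2 = a0, sd_db = 0, seed = 3)
  expect_equal(d0$t_e_min, a0 * d0$x_mm^2, tolerance = 1e-12)
  dN <- synth_effect_time_dataset(n = 1e4, a0_min_mm2 = a0, sd_db = 3, seed = 4)
  eps <- 20 * log10(dN$t_e_min / (a0 * dN$x_mm^2))
  expect_lt(abs(mean(eps)), 3 * 3 / sqrt(1e4))
})

test_that("wall-motion fixtures have zero-mean periodic motion and a silent zero-amplitude limit", {
  w <- synth_wall_motion(a_peak_um = 0)
  x <- seq(0, 3, by = 0.05)
  expect_true(all(wall_motion(w, x, 0.3e-3)$displacement_um == 0))
  ws <- synth_wall_motion(type = "standing")
  N <- 64
  disp <- vapply(seq_len(N) - 1, function(k) {
    wall_motion(ws, x, k * ws$period_s / N)$displacement_um
  }, numeric(length(x)))
  expect_lt(max(abs(rowMeans(disp))), 1e-12 * ws$a_peak_um)
})

test_that("the bimodal generator mode produces curves the pipeline flags", {
  cfg <- synth_config(seed = 8, bimodal = TRUE, t_e_min = c(2, 3, 4),
                      n_sequences = 12, n_baseline_seq = 2)
  syn <- synth_recording(cfg)
  et <- effect_time(driven_response_curve(segment_responses(syn$recording),
                                          syn$recording$t0_s))
  expect_true(any(et$bimodal))
})

test_that("the full pipeline recovers ground-truth effect times within one sequence", {
  for (s in 1:2) {
    syn <- synth_recording(synth_config(seed = s))
    et <- effect_time(driven_response_curve(segment_responses(syn$recording),
                                            syn$recording$t0_s))
    err_s <- abs(et$t_e_min - syn$truth$t_e_min) * 60
    expect_true(all(is.finite(err_s)))
    expect_lt(max(err_s), 57.2)
  }
})
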