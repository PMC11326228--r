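test_that("Teager operator: constants vanish, sinusoids give a phase-free constant, amplitude enters quadratically", {
  expect_equal(max(abs(teager_energy(rep(2.5, 50)))), 0)
  Om <- 0.37; A <- 1.7; phi <- 0.9
  x <- A * sin(Om * (1:500) + phi)
  psi <- teager_energy(x)
  expect_lt(max(abs(psi / (A^2 * sin(Om)^2) - 1)), 1e-10)
  expect_equal(teager_energy(2 * x), 4 * psi, tolerance = 1e-12)
  expect_error(teager_energy(c(1, 2)), "3 samples")
})

test_that("the stimulus schedule tiles 52 segments into 57.2-s sequences", {
  sch <- stimulus_schedule(3)
  expect_equal(nrow(sch), 3 * 52)
  expect_equal(max(sch$t_end_s), 3 * 57.2)
  one <- sch[sch$sequence == 1, ]
  expect_equal(table(one$label)[["noise"]], 48)
  expect_equal(table(one$label)[["pause"]], 1)
  expect_equal(table(one$label)[["tone"]], 3)
  expect_equal(diff(range(one$t_end_s - one$t_start_s)), 0)
})

test_that("segment_responses drops incomplete trailing sequences and rejects short records", {
  syn <- synth_recording(synth_config(n_sequences = 3, n_baseline_seq = 1,
                                      t_e_min = c(0.5, 0.8, 1)))
  rec <- syn$recording
  # truncate half of the final sequence
  n_keep <- floor(nrow(rec$waveform) - 26 * 1.1 * rec$fs_hz)
  rec_tr <- neural_recording(rec$waveform[1:n_keep, ], rec$fs_hz, rec$cf_khz,
                             rec$schedule, rec$t0_s)
  expect_warning(seg <- segment_responses(rec_tr), "incomplete")
  expect_equal(max(seg$sequence), 2)
  rec_short <- neural_recording(rec$waveform[1:1000, ], rec$fs_hz, rec$cf_khz,
                                rec$schedule, rec$t0_s)
  expect_error(segment_responses(rec_short), "shorter")
})

test_that("driven responses vanish when tones carry no signal and normalise to unit baseline", {
  cfg <- synth_config(seed = 3, n_sequences = 6, n_baseline_seq = 2,
                      t_e_min = c(1, 2, 3), snr = 5, noise_pip_snr = 0)
  syn <- synth_recording(cfg)
  seg <- segment_responses(syn$recording)
  cur <- driven_response_curve(seg, syn$recording$t0_s)
  pre <- cur[cur$t_min < 0, ]
  expect_equal(mean(pre$normalized), 1, tolerance = 1e-9)  # by construction
  # a channel with zero driven amplitude: tone statistics equal pause statistics
  rec0 <- syn$recording
  wf <- matrix(rnorm(length(rec0$waveform)), nrow(rec0$waveform))
  rec_null <- neural_recording(wf, rec0$fs_hz, rec0$cf_khz, rec0$schedule,
                               rec0$t0_s)
  seg0 <- segment_responses(rec_null)
  tones <- seg0[seg0$label == "tone" & seg0$tone_channel == seg0$channel, ]
  pauses <- seg0[seg0$label == "pause" & seg0$channel == 1, ]
  expect_lt(abs(mean(tones$mean_teager) - mean(pauses$mean_teager)),
            4 * stats::sd(tones$mean_teager))
})

test_that("effect_time interpolates sustained crossings and sets quality flags", {
  # clean step from 1 to 0 between t = 2 and t = 3
  y <- c(1, 1, 1, 1, 1, 0, 0, 0)
  et <- effect_time(make_curve(y))
  expect_equal(et$t_e_min, 2 + 0.25, tolerance = 1e-12)  # crossing of 0.75
  expect_false(et$never_crossed); expect_false(et$bimodal)
  # never crossing
  et2 <- effect_time(make_curve(c(1, 1, 0.95, 0.9, 0.85, 0.8)))
  expect_true(et2$never_crossed)
  expect_true(is.na(et2$t_e_min))
  # a single noise dip is not sustained
  et3 <- effect_time(make_curve(c(1, 1, 1, 0.6, 1, 1, 0.5, 0.4, 0.3)))
  expect_equal(et3$t_e_min, 3 + (1 - 0.75) / (1 - 0.5), tolerance = 1e-12)
  # bimodal rebound after the first sustained crossing
  et4 <- effect_time(make_curve(c(1, 1, 1, 0.6, 0.5, 0.9, 0.85, 0.3, 0.2, 0.1)))
  expect_true(et4$bimodal)
  expect_error(effect_time(make_curve(c(1, 1, 1, 0.5))[1:3, ]), "post-application")
})

test_that("diffusion-trend fitting recovers noiseless data exactly and rejects degenerate input", {
  a0 <- 1.3
  d <- tibble::tibble(x_mm = c(1, 2, 4, 7), t_e_min = a0 * c(1, 2, 4, 7)^2)
  fit <- fit_diffusion_trend(d)
  expect_equal(fit$a_min_mm2, a0, tolerance = 1e-12)
  expect_equal(predict(fit, 3), a0 * 9, tolerance = 1e-12)
  # implied diffusivity matches the closed-form effect time
  expect_equal(diffusion_effect_time(5, fit$d_eff_m2_s), a0 * 25, tolerance = 1e-9)
  expect_error(fit_diffusion_trend(d[1, ]), "at least 3")
  expect_error(fit_diffusion_trend(tibble::tibble(x_mm = c(1, 1, 1),
                                                  t_e_min = c(1, 2, 3))),
               "distinct")
  gl <- glance(fit)
  expect_equal(gl$sigma_db, 0, tolerance = 1e-9)
})

test_that("trend recovery from scattered data is within 10% (50 seeded replicates)", {
  a0 <- 1.57
  ok <- vapply(1:50, function(s) {
    d <- synth_effect_time_dataset(n = 48, a0_min_mm2 = a0,
                                   sd_db = 20 * log10(exp(0.1)), seed = s)
    abs(fit_diffusion_trend(d)$a_min_mm2 / a0 - 1) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("dB normalisation has the stated fixed points and exact inverse", {
  expect_equal(effect_time_db(5, 5), 0)
  expect_equal(effect_time_db(2, 1), 6.0206, tolerance = 1e-4)
  expect_equal(effect_time_db(0.5, 5), -20)
  db <- effect_time_db(7.3, 2.1)
  expect_equal(2.1 * 10^(db / 20), 7.3, tolerance = 1e-12)
  expect_error(effect_time_db(-1, 5), "positive")
})

test_that("group comparison reproduces the Welch t-test and validates group sizes", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 4)
  expect_equal(compare_groups(a, b)$p_value, 1)
  set.seed(42)
  g0 <- rnorm(10, 0, 0.1); g10 <- rnorm(10, 10, 0.1)
  res <- compare_groups(g0, g10)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$p_value, t.test(g0, g10)$p.value)
  expect_lt(res$ci_lo_a, res$mean_a); expect_gt(res$ci_hi_a, res$mean_a)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("DPOAE sweep analysis recovers a known distortion level within 1 dB", {
  pres <- synth_dpoae_sweep(dp_level_db = -10, noise_sd = 0.02, seed = 5)
  lv <- dpoae_level_sweep(pres, fs_hz = 24000)
  inner <- lv[lv$t_s > 0.4 & lv$t_s < 3.6, ]
  expect_lt(max(abs(inner$level_db - (-10))), 1)
  expect_true(all(inner$noise_db < inner$level_db - 10))
})

test_that("identical even and odd presentations give a null noise floor, and noise-only sweeps stay at the floor", {
  one <- synth_dpoae_sweep(dp_level_db = -20, noise_sd = 0, n_pres = 1, seed = 1)
  pres <- cbind(one, one, one, one)
  lv <- dpoae_level_sweep(pres, fs_hz = 24000)
  expect_true(all(!is.finite(lv$noise_db) | lv$noise_db < -250))
  # no distortion component: estimated level within a few dB of the floor
  pres0 <- synth_dpoae_sweep(dp_level_db = -Inf, noise_sd = 0.05, seed = 7)
  lv0 <- dpoae_level_sweep(pres0, fs_hz = 24000)
  inner <- lv0[lv0$t_s > 0.4 & lv0$t_s < 3.6, ]
  expect_lt(mean(inner$level_db), mean(inner$noise_db) + 3)
})
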