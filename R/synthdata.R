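#' Configuration of the synthetic recording generator
#'
#' Generates multi-channel neural recordings with the statistical structure
#' the analysis chain assumes: the 57.2-s sequence protocol (48 noise pips,
#' one pause, one CF tone pip per channel, 1.1 s each), spontaneous activity
#' as white noise, per-channel driven CF-tone responses whose Teager power
#' decays logistically after drug onset and crosses 75% of baseline at the
#' ground-truth effect time, and per-segment level jitter.
#'
#' Desk-scale defaults: sampling at 4 kHz with apical-channel CFs (1.5, 0.9,
#' 0.5 kHz) and effect times of a few minutes, matching the faster end of
#' in-vivo sound-case decays while keeping a full recording tractable.
#'
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @param fs_hz Sampling rate, Hz.
#' @param cf_khz Per-channel CFs, kHz (each must lie in (0.05, 0.45) * fs).
#' @param t_e_min Ground-truth per-channel effect times, minutes after
#'   application.
#' @param n_baseline_seq Number of pre-application sequences (sets the
#'   application time `t0`).
#' @param n_sequences Total number of sequences.
#' @param decay_tau_min Logistic decay time constant, min.
#' @param spont_sd Spontaneous waveform standard deviation (arbitrary units).
#' @param snr Driven-to-spontaneous Teager power ratio of the CF-tone
#'   response at baseline.
#' @param jitter_db Per-segment response level jitter (dB standard
#'   deviation).
#' @param noise_pip_snr Teager power ratio of the broadband driven response
#'   during noise pips (not used by the analysis; realism only).
#' @param bimodal Add a transient rebound after the first decay so that the
#'   bimodal-decay flag is exercised.
#' @return A `synth_config` object.
#' @export
synth_config <- function(seed = 1, fs_hz = 4000,
                         cf_khz = c(1.5, 0.9, 0.5),
                         t_e_min = c(3, 5, 8),
                         n_baseline_seq = 4,
                         n_sequences = 16,
                         decay_tau_min = 1,
                         spont_sd = 1, snr = 5, jitter_db = 0.25,
                         noise_pip_snr = 2, bimodal = FALSE) {
  stopifnot(length(cf_khz) == length(t_e_min))
  om <- cf_khz * 1000 / fs_hz
  if (any(om <= 0.05) || any(om >= 0.45)) {
    stop("channel CFs must lie within (0.05, 0.45) of the sampling rate",
         call. = FALSE)
  }
  stopifnot(n_sequences > n_baseline_seq)
  structure(
    list(seed = as.integer(seed), fs_hz = fs_hz, cf_khz = cf_khz,
         t_e_min = t_e_min, n_baseline_seq = n_baseline_seq,
         n_sequences = n_sequences, decay_tau_min = decay_tau_min,
         spont_sd = spont_sd, snr = snr, jitter_db = jitter_db,
         noise_pip_snr = noise_pip_snr, bimodal = isTRUE(bimodal)),
    class = "synth_config")
}

# normalised driven-power decay: logistic crossing 0.75 at t_e, optional
# rebound bump for bimodal curves; t in minutes after application
decay_profile <- function(t_min, t_e, tau, bimodal = FALSE) {
  t_mid <- t_e + tau * log(3)
  g <- 1 / (1 + exp((t_min - t_mid) / tau))
  if (bimodal) {
    g <- pmin(1, g + 0.8 * exp(-0.5 * ((t_min - t_e - 3 * tau) / tau)^2))
  }
  g
}

#' Generate a synthetic neural recording
#'
#' @param config A [synth_config()].
#' @return A list with `recording` (a [neural_recording()]) and `truth`
#'   (tibble of per-channel ground-truth effect times).
#' @examples
#' synth <- synth_recording(synth_config(n_sequences = 4, t_e_min = c(1, 2, 3)))
#' synth$truth
#' @export
synth_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_hz
  nch <- length(config$cf_khz)
  sch <- stimulus_schedule(config$n_sequences, n_channels = nch)
  seq_dur <- max(sch$t_end_s[sch$sequence == 1])
  t0_s <- config$n_baseline_seq * seq_dur
  n <- round(max(sch$t_end_s) * fs)
  with_seed_(config$seed, {
    wf <- matrix(rnorm(n * nch, sd = config$spont_sd), n, nch)
    amp0 <- config$spont_sd * sqrt(config$snr) /
      abs(sin(2 * pi * config$cf_khz * 1000 / fs))
    for (k in seq_len(nrow(sch))) {
      i0 <- floor(sch$t_start_s[k] * fs) + 1L
      i1 <- min(n, floor(sch$t_end_s[k] * fs))
      idx <- i0:i1
      t_rel_min <- ((sch$t_start_s[k] + sch$t_end_s[k]) / 2 - t0_s) / 60
      if (sch$label[k] == "tone") {
        ch <- sch$tone_channel[k]
        g <- decay_profile(t_rel_min, config$t_e_min[ch],
                           config$decay_tau_min, config$bimodal)
        jit <- 10^(rnorm(1, sd = config$jitter_db) / 20)
        a <- amp0[ch] * sqrt(g) * jit
        wf[idx, ch] <- wf[idx, ch] +
          a * sin(2 * pi * config$cf_khz[ch] * 1000 * (idx - 1) / fs)
      } else if (sch$label[k] == "noise") {
        for (ch in seq_len(nch)) {
          g <- decay_profile(t_rel_min, config$t_e_min[ch],
                             config$decay_tau_min, config$bimodal)
          sd_add <- config$spont_sd * sqrt(config$noise_pip_snr * g)
          wf[idx, ch] <- wf[idx, ch] + rnorm(length(idx), sd = sd_add)
        }
      }
    }
    list(
      recording = neural_recording(wf, fs, config$cf_khz, sch, t0_s),
      truth = tibble(channel = seq_len(nch), cf_khz = config$cf_khz,
                     t_e_min = config$t_e_min))
  })
}

#' Synthetic effect-time dataset on a diffusion trend
#'
#' Draws places uniformly over `x_range_mm` and effect times
#' `t_E = a0 x^2 10^(eps/20)` with `eps ~ Normal(0, sd_db)`: data scattered
#' log-normally about the one-dimensional diffusion trend, as the silence-case
#' measurements are. The default scale `a0 = 1.57 min/mm^2` corresponds to
#' kainic-acid-scale diffusion (`D = 8e-10 m^2/s` at the 1% threshold) and
#' puts the 6.5-mm place near 55 minutes.
#'
#' @param n Number of observations.
#' @param a0_min_mm2 True trend scale, min/mm^2.
#' @param sd_db Log-normal scatter, dB.
#' @param x_range_mm Place range sampled, mm.
#' @param seed RNG seed.
#' @return Tibble with `x_mm`, `t_e_min`.
#' @export
synth_effect_time_dataset <- function(n = 48, a0_min_mm2 = 1.57, sd_db = 3,
                                      x_range_mm = c(1, 11), seed = 1) {
  stopifnot(n >= 3, a0_min_mm2 > 0, sd_db >= 0)
  with_seed_(seed, {
    x <- runif(n, x_range_mm[1], x_range_mm[2])
    eps <- rnorm(n, sd = sd_db)
    tibble(x_mm = x, t_e_min = a0_min_mm2 * x^2 * 10^(eps / 20))
  })
}

#' Parametric wall-motion fixture for the flow solver
#'
#' A single-frequency peristaltic wave with the traveling-wave envelope and
#' phase machinery of [traveling_wave()] but parameterised directly (no
#' place-frequency map or level calibration), for driving the flow solver in
#' tests and demonstrations. The standing variant freezes the spatial phase
#' into the envelope (`A(x) cos(phi(x)) cos(omega t)`): matched amplitude
#' and wavenumber content, zero phase propagation.
#'
#' @param a_peak_um Peak displacement amplitude, micrometres.
#' @param f_hz Frequency, Hz.
#' @param x_peak_mm Envelope peak (CF place surrogate), mm.
#' @param domain_mm Domain length, mm.
#' @param type `"traveling"` or `"standing"`.
#' @param tail_level,peak_width_mm,stall_margin_mm Envelope shape, as in
#'   [traveling_wave()].
#' @param c_base_mm_s,c_peak_mm_s,c_profile_exp Phase-velocity profile, as in
#'   [traveling_wave()].
#' @return A `wall_motion_field`.
#' @export
synth_wall_motion <- function(a_peak_um = 4, f_hz = 1000, x_peak_mm = 2.2,
                              domain_mm = 3, type = c("traveling", "standing"),
                              tail_level = 0.2, peak_width_mm = 0.4,
                              stall_margin_mm = 0.5,
                              c_base_mm_s = 10000, c_peak_mm_s = 500,
                              c_profile_exp = 2) {
  type <- match.arg(type)
  w <- new_wall_motion_field(
    f_hz = f_hz, a_peak_um = a_peak_um, x_peak_mm = x_peak_mm,
    x_max_mm = domain_mm, tail_level = tail_level,
    peak_width_mm = peak_width_mm, stall_margin_mm = stall_margin_mm,
    c_base_mm_s = c_base_mm_s, c_peak_mm_s = c_peak_mm_s,
    c_profile_exp = c_profile_exp,
    standing = type == "standing")
  w
}

#' Synthetic swept-tone DPOAE presentations
#'
#' Builds presentation-by-presentation microphone signals containing the two
#' swept primaries, a 2f1-f2 distortion component at a prescribed level, and
#' independent white noise per presentation, for exercising
#' [dpoae_level_sweep()].
#'
#' @param dp_level_db Distortion-product level, dB re unit amplitude
#'   (`-Inf` for no distortion component).
#' @param primary_level_db Primary-tone level, dB re unit amplitude.
#' @param noise_sd Per-presentation white-noise standard deviation.
#' @param n_pres Number of presentations.
#' @param fs_hz,f2_start_hz,f2_end_hz,sweep_s,ratio Sweep parameters, as in
#'   [dpoae_level_sweep()].
#' @param seed RNG seed.
#' @return Numeric matrix, samples by presentations.
#' @export
synth_dpoae_sweep <- function(dp_level_db = -10, primary_level_db = 40,
                              noise_sd = 0.05, n_pres = 10,
                              fs_hz = 24000, f2_start_hz = 500,
                              f2_end_hz = 10000, sweep_s = 4, ratio = 1.25,
                              seed = 1) {
  n <- round(sweep_s * fs_hz)
  tv <- (seq_len(n) - 1) / fs_hz
  slope <- (f2_end_hz - f2_start_hz) / sweep_s
  ph2 <- 2 * pi * (f2_start_hz * tv + 0.5 * slope * tv^2)
  ph1 <- ph2 / ratio
  phd <- (2 / ratio - 1) * ph2
  base <- 10^(primary_level_db / 20) * (cos(ph1) + cos(ph2))
  if (is.finite(dp_level_db)) {
    base <- base + 10^(dp_level_db / 20) * cos(phd)
  }
  with_seed_(seed, {
    base + matrix(rnorm(n * n_pres, sd = noise_sd), n, n_pres)
  })
}
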