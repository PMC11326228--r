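#' Teager energy operator
#'
#' Discrete quadratic energy operator used to quantify multi-unit neural
#' activity: `psi[n] = x[n]^2 - x[n-1] x[n+1]` for interior samples (the two
#' end samples are dropped). For a sinusoid `A sin(Omega n + phi)` the
#' operator returns the constant `A^2 sin(Omega)^2`, independent of phase.
#'
#' @param x Numeric waveform with at least 3 samples.
#' @return Numeric vector of length `length(x) - 2`.
#' @examples
#' teager_energy(sin(0.3 * (1:100)))  # constant sin(0.3)^2
#' @export
teager_energy <- function(x) {
  if (!is.numeric(x) || length(x) < 3) {
    stop("`x` must be a numeric waveform with at least 3 samples", call. = FALSE)
  }
  n <- length(x)
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' Stimulus schedule of the recording protocol
#'
#' One sequence is 48 noise pips, one silent pause, and one CF tone pip per
#' probe channel (three by default), each segment lasting 1.1 s: 52 segments,
#' 57.2 s. The pause monitors spontaneous activity; the 35-dB CF tones
#' monitor driven responses.
#'
#' @param n_sequences Number of repeated sequences.
#' @param n_channels Number of probe channels (one CF tone pip each).
#' @param seg_s Segment duration in seconds.
#' @param n_noise Number of noise pips per sequence.
#' @return Tibble with `sequence`, `segment`, `label` (noise/pause/tone),
#'   `tone_channel` (NA except for tone segments), `t_start_s`, `t_end_s`.
#' @export
stimulus_schedule <- function(n_sequences, n_channels = 3, seg_s = 1.1,
                              n_noise = 48) {
  stopifnot(n_sequences >= 1, n_channels >= 1)
  per <- n_noise + 1L + n_channels
  lab <- c(rep("noise", n_noise), "pause", rep("tone", n_channels))
  tch <- c(rep(NA_integer_, n_noise + 1L), seq_len(n_channels))
  seq_id <- rep(seq_len(n_sequences), each = per)
  seg <- rep(seq_len(per), n_sequences)
  start <- (seq_along(seq_id) - 1) * seg_s
  tibble(sequence = seq_id, segment = seg,
         label = rep(lab, n_sequences),
         tone_channel = rep(tch, n_sequences),
         t_start_s = start, t_end_s = start + seg_s)
}

#' Multi-channel neural recording container
#'
#' @param waveform Numeric matrix, samples by channels.
#' @param fs_hz Sampling rate, Hz; must exceed twice the highest channel CF.
#' @param cf_khz Per-channel characteristic frequencies, kHz.
#' @param schedule A [stimulus_schedule()] tibble tiling the recording.
#' @param t0_s Drug-application time, s from recording start.
#' @return A `neural_recording` object.
#' @export
neural_recording <- function(waveform, fs_hz, cf_khz, schedule, t0_s) {
  if (is.vector(waveform)) waveform <- matrix(waveform, ncol = 1)
  stopifnot(is.matrix(waveform), is.numeric(waveform))
  if (fs_hz <= 2 * max(cf_khz) * 1000) {
    stop("sampling rate must exceed twice the highest channel CF", call. = FALSE)
  }
  stopifnot(length(cf_khz) == ncol(waveform))
  structure(
    list(waveform = waveform, fs_hz = fs_hz, cf_khz = cf_khz,
         schedule = schedule, t0_s = t0_s),
    class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat(sprintf(
    "<neural_recording> %d ch x %0.4g s at %g Hz; CFs %s kHz; drug at %0.4g s\n",
    ncol(x$waveform), nrow(x$waveform) / x$fs_hz, x$fs_hz,
    paste(x$cf_khz, collapse = "/"), x$t0_s))
  invisible(x)
}

#' Per-segment Teager response amplitudes
#'
#' Splits each channel's waveform along the stimulus schedule and takes the
#' mean Teager energy of every segment as the response-amplitude measure.
#' A trailing incomplete sequence is excluded with a warning.
#'
#' @param recording A [neural_recording()].
#' @return Tibble with `channel`, `sequence`, `segment`, `label`,
#'   `tone_channel`, `t_mid_s`, `mean_teager`.
#' @export
segment_responses <- function(recording) {
  stopifnot(inherits(recording, "neural_recording"))
  sch <- recording$schedule
  fs <- recording$fs_hz
  n <- nrow(recording$waveform)
  t_rec <- n / fs
  complete <- vapply(split(sch$t_end_s, sch$sequence), max, numeric(1)) <=
    t_rec + 0.5 / fs
  if (!any(complete)) {
    stop("recording is shorter than one full sequence", call. = FALSE)
  }
  if (!all(complete)) {
    warning(sprintf("dropping %d incomplete trailing sequence(s)",
                    sum(!complete)), call. = FALSE)
    sch <- sch[sch$sequence %in% as.integer(names(complete)[complete]), ]
  }
  nch <- ncol(recording$waveform)
  i0 <- pmax(1L, floor(sch$t_start_s * fs) + 1L)
  i1 <- pmin(n, floor(sch$t_end_s * fs))
  res <- lapply(seq_len(nch), function(ch) {
    w <- recording$waveform[, ch]
    mt <- vapply(seq_along(i0), function(k) {
      mean(teager_energy(w[i0[k]:i1[k]]))
    }, numeric(1))
    tibble(channel = ch, sequence = sch$sequence, segment = sch$segment,
           label = sch$label, tone_channel = sch$tone_channel,
           t_mid_s = (sch$t_start_s + sch$t_end_s) / 2, mean_teager = mt)
  })
  dplyr::bind_rows(res)
}

#' Driven response curves
#'
#' The driven response of a channel in each sequence is the mean Teager
#' amplitude of its CF-tone segment minus that of the silent pause
#' (spontaneous activity). Curves are normalised by the pre-application
#' baseline (mean driven response over all sequences before `t0`).
#'
#' @param segments Output of [segment_responses()].
#' @param t0_s Drug-application time, s.
#' @param smooth Width (in sequences) of an optional centred moving average
#'   applied to the normalised curve; 0 (default) disables smoothing.
#' @return Tibble with `channel`, `sequence`, `t_min` (minutes relative to
#'   `t0_s`), `driven`, `normalized`, `baseline`.
#' @export
driven_response_curve <- function(segments, t0_s, smooth = 0) {
  stopifnot(is.data.frame(segments))
  pauses <- segments[segments$label == "pause", c("channel", "sequence", "mean_teager")]
  names(pauses)[3] <- "spont"
  tones <- segments[segments$label == "tone" &
                      segments$tone_channel == segments$channel, ]
  if (!nrow(tones) || !nrow(pauses)) {
    stop("schedule must contain a pause and a per-channel tone segment",
         call. = FALSE)
  }
  cur <- dplyr::inner_join(
    tones[, c("channel", "sequence", "t_mid_s", "mean_teager")],
    pauses, by = c("channel", "sequence"))
  cur$driven <- cur$mean_teager - cur$spont
  cur$t_min <- (cur$t_mid_s - t0_s) / 60
  out <- dplyr::group_modify(dplyr::group_by(cur, .data$channel), function(d, key) {
    pre <- d$driven[d$t_min < 0]
    if (!length(pre)) {
      stop("no pre-application sequences: cannot normalise", call. = FALSE)
    }
    base <- mean(pre)
    if (base <= 0) stop("non-positive baseline driven response", call. = FALSE)
    d$normalized <- d$driven / base
    if (smooth > 1) {
      k <- as.integer(smooth)
      d$normalized <- stats::filter(d$normalized, rep(1 / k, k), sides = 2) |>
        as.numeric()
      # ends of the moving average are left unsmoothed
      miss <- is.na(d$normalized)
      d$normalized[miss] <- d$driven[miss] / base
    }
    d$baseline <- base
    d
  })
  dplyr::select(dplyr::ungroup(out), "channel", "sequence", "t_min",
                "driven", "normalized", "baseline")
}

#' Effect time of a response curve
#'
#' The effect time is the latency after drug application at which the
#' normalised driven response first drops below the criterion (75% of
#' baseline) in a sustained way (below criterion for at least `sustain`
#' consecutive sequences), linearly interpolated between sequences. Curves
#' that re-rise above the criterion by more than 0.1 after the first
#' sustained crossing are flagged bimodal; curves that never cross are
#' flagged and carry no numeric effect time.
#'
#' @param curve Output of [driven_response_curve()].
#' @param criterion Crossing criterion as a fraction of baseline.
#' @param sustain Number of consecutive below-criterion sequences required.
#' @return Tibble with `channel`, `t_e_min`, `never_crossed`, `bimodal`.
#' @export
effect_time <- function(curve, criterion = 0.75, sustain = 2) {
  stopifnot(is.data.frame(curve), criterion > 0, criterion < 1)
  one <- function(d, key) {
    d <- d[order(d$t_min), ]
    post <- d[d$t_min > 0, ]
    if (nrow(post) < 2) {
      stop("need at least two post-application sequences", call. = FALSE)
    }
    y <- d$normalized; t <- d$t_min
    below <- y < criterion
    run_ok <- function(k) {
      kk <- k:min(k + sustain - 1L, length(y))
      length(kk) >= sustain && all(below[kk])
    }
    cand <- which(below & t > 0)
    k1 <- NA_integer_
    for (k in cand) if (run_ok(k)) { k1 <- k; break }
    if (is.na(k1)) {
      return(tibble(t_e_min = NA_real_, never_crossed = TRUE, bimodal = FALSE))
    }
    # interpolate from the previous (above-criterion) sample
    if (k1 == 1L || y[k1 - 1L] < criterion) {
      te <- max(t[k1], 0)
    } else {
      te <- t[k1 - 1L] + (y[k1 - 1L] - criterion) / (y[k1 - 1L] - y[k1]) *
        (t[k1] - t[k1 - 1L])
      te <- max(te, 0)
    }
    bimodal <- any(y[seq_along(y) > k1] > criterion + 0.1)
    tibble(t_e_min = te, never_crossed = FALSE, bimodal = bimodal)
  }
  out <- dplyr::group_modify(dplyr::group_by(curve, .data$channel), one)
  dplyr::ungroup(out)
}

#' Fit the one-dimensional diffusion trend to effect times
#'
#' Fits `t_E = a x^2`, the first-passage scaling of one-dimensional
#' diffusion to a fixed concentration threshold
#' (`t = x^2 / (4 D erfcinv(f_thr)^2)`), by least squares on `log t_E`
#' (multiplicative residuals, matching the dB scale used for normalised
#' effect times). The single scale parameter `a` implies an effective
#' diffusivity `D_eff = 1 / (4 a erfcinv(f_thr)^2)`.
#'
#' @param data Data frame of effect-time observations.
#' @param x_col,te_col Column names of place (mm) and effect time (min).
#' @param f_thr Threshold fraction used to convert `a` to `D_eff`.
#' @return A `diffusion_trend` object with [tidy()], [glance()], `predict()`
#'   and [autoplot()] methods.
#' @export
fit_diffusion_trend <- function(data, x_col = "x_mm", te_col = "t_e_min",
                                f_thr = 0.01) {
  stopifnot(is.data.frame(data), x_col %in% names(data), te_col %in% names(data))
  x <- data[[x_col]]; te <- data[[te_col]]
  keep <- is.finite(x) & is.finite(te)
  x <- x[keep]; te <- te[keep]
  if (length(x) < 3 || length(unique(x)) < 3) {
    stop("need at least 3 observations with distinct places", call. = FALSE)
  }
  if (any(x <= 0) || any(te <= 0)) {
    stop("places and effect times must be positive", call. = FALSE)
  }
  resid_log <- log(te) - 2 * log(x)
  log_a <- mean(resid_log)
  a <- exp(log_a)                       # min / mm^2
  beta <- erfcinv_(f_thr)
  d_eff_mm2_min <- 1 / (4 * a * beta^2)
  sigma_db <- stats::sd(resid_log) * 20 / log(10)
  structure(
    list(a_min_mm2 = a, f_thr = f_thr,
         d_eff_m2_s = d_eff_mm2_min * 1e-6 / 60,
         sigma_db = sigma_db, n = length(x),
         data = tibble(x_mm = x, t_e_min = te)),
    class = "diffusion_trend")
}

#' @export
print.diffusion_trend <- function(x, ...) {
  cat(sprintf(
    "<diffusion_trend> t_E = %0.4g min/mm^2 * x^2 (D_eff = %0.3g m^2/s, n = %d, sigma = %0.2f dB)\n",
    x$a_min_mm2, x$d_eff_m2_s, x$n, x$sigma_db))
  invisible(x)
}

#' Predicted trend effect time
#'
#' @param object A `diffusion_trend`.
#' @param x_mm Places, mm.
#' @param ... Unused.
#' @return Trend effect times, min.
#' @export
predict.diffusion_trend <- function(object, x_mm, ...) {
  object$a_min_mm2 * x_mm^2
}

#' @export
tidy.diffusion_trend <- function(x, ...) {
  tibble(term = c("a_min_mm2", "d_eff_m2_s"),
         estimate = c(x$a_min_mm2, x$d_eff_m2_s))
}

#' @export
glance.diffusion_trend <- function(x, ...) {
  tibble(a_min_mm2 = x$a_min_mm2, d_eff_m2_s = x$d_eff_m2_s,
         sigma_db = x$sigma_db, n = x$n)
}

#' Effect time in dB relative to the diffusion trend
#'
#' `t_E(dB) = 20 log10(t_E / t_Trend)`: 0 dB lies on the trend, negative
#' values indicate faster-than-diffusion delivery. Exactly inverted by
#' `t_E = t_Trend * 10^(dB/20)`.
#'
#' @param t_e_min Observed effect times, min (positive).
#' @param t_trend_min Trend effect times at the same places, min (positive).
#' @return Effect times in dB.
#' @export
effect_time_db <- function(t_e_min, t_trend_min) {
  if (any(t_e_min <= 0) || any(t_trend_min <= 0)) {
    stop("effect times must be positive", call. = FALSE)
  }
  20 * log10(t_e_min / t_trend_min)
}

#' Compare effect-time groups
#'
#' Two-tailed Welch t-test between two groups of dB-normalised effect times,
#' with per-group means and 95% confidence intervals.
#'
#' @param db_a,db_b Numeric vectors of dB effect times (n >= 2 each).
#' @return One-row tibble with group statistics, `t`, `df` and `p_value`.
#' @export
compare_groups <- function(db_a, db_b) {
  if (length(db_a) < 2 || length(db_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(db_a, db_b, alternative = "two.sided", var.equal = FALSE)
  ci <- function(v) {
    m <- mean(v); s <- stats::sd(v) / sqrt(length(v))
    m + c(-1, 1) * stats::qt(0.975, length(v) - 1) * s
  }
  ca <- ci(db_a); cb <- ci(db_b)
  tibble(n_a = length(db_a), n_b = length(db_b),
         mean_a = mean(db_a), mean_b = mean(db_b),
         ci_lo_a = ca[1], ci_hi_a = ca[2],
         ci_lo_b = cb[1], ci_hi_b = cb[2],
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

#' DPOAE level estimation from swept primaries
#'
#' Estimates the 2f1-f2 distortion-product level along a linear f2 sweep
#' (f2 = `ratio` * f1) by least-squares fitting a sinusoid at the
#' instantaneous distortion frequency to the presentation-averaged microphone
#' signal in a Hann window stepped along the sweep. The noise floor is the
#' same analysis applied to the "null" response, the difference between the
#' averages of even- and odd-numbered presentations (halved).
#'
#' @param presentations Numeric matrix (samples by presentations) or vector
#'   (single presentation; no noise floor is then available).
#' @param fs_hz Sampling rate, Hz.
#' @param f2_start_hz,f2_end_hz Linear f2 sweep limits, Hz.
#' @param sweep_s Sweep duration, s.
#' @param ratio Primary ratio f2/f1.
#' @param window_s,step_s Hann analysis window length and hop, s.
#' @return Tibble with `t_s`, `f2_hz`, `fdp_hz`, `level_db` (dB re unit
#'   amplitude), `noise_db` (NA without >= 2 presentations).
#' @export
dpoae_level_sweep <- function(presentations, fs_hz, f2_start_hz = 500,
                              f2_end_hz = 10000, sweep_s = 4, ratio = 1.25,
                              window_s = 0.1, step_s = 0.02) {
  if (is.vector(presentations)) presentations <- matrix(presentations, ncol = 1)
  stopifnot(is.matrix(presentations), nrow(presentations) >= 2)
  npres <- ncol(presentations)
  nsamp <- nrow(presentations)
  if (nsamp < round(window_s * fs_hz)) {
    stop("presentations shorter than the analysis window", call. = FALSE)
  }
  avg <- rowMeans(presentations)
  null <- if (npres >= 2) {
    ev <- seq(2, npres, by = 2); od <- seq(1, npres, by = 2)
    (rowMeans(presentations[, ev, drop = FALSE]) -
       rowMeans(presentations[, od, drop = FALSE])) / 2
  } else NULL
  slope <- (f2_end_hz - f2_start_hz) / sweep_s
  kdp <- 2 / ratio - 1                      # fdp = kdp * f2
  tvec <- (seq_len(nsamp) - 1) / fs_hz
  phase <- 2 * pi * kdp * (f2_start_hz * tvec + 0.5 * slope * tvec^2)
  nwin <- round(window_s * fs_hz)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))
  starts <- seq(0, sweep_s - window_s, by = step_s)
  fit_level <- function(y, i0) {
    ii <- i0 + seq_len(nwin)
    ph <- phase[ii]
    X <- cbind(cos(ph), sin(ph))
    wX <- X * hann
    ab <- solve(crossprod(wX, X), crossprod(wX, y[ii]))
    20 * log10(sqrt(sum(ab^2)))
  }
  out <- lapply(starts, function(s0) {
    i0 <- round(s0 * fs_hz)
    if (i0 + nwin > nsamp) return(NULL)
    tc <- s0 + window_s / 2
    f2c <- f2_start_hz + slope * tc
    tibble(t_s = tc, f2_hz = f2c, fdp_hz = kdp * f2c,
           level_db = fit_level(avg, i0),
           noise_db = if (is.null(null)) NA_real_ else fit_level(null, i0))
  })
  dplyr::bind_rows(out)
}
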