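#' Parametric cochlear traveling-wave surrogate
#'
#' Builds a time-periodic, kinematic description of the peristaltic motion of
#' the top wall of the Corti fluid: an amplitude envelope that rises along a
#' long shallow basal tail, peaks at the CF place of the stimulus, and is
#' tapered to zero shortly apical of the peak (the wave "stalls"); and a phase
#' profile whose local phase velocity decays toward the apex. This surrogate
#' stands in for a full organ-of-Corti vibration model: the downstream flow
#' solver only consumes wall motion as a kinematic boundary condition.
#'
#' The displacement field is
#' `u_m(x, t) = A(x) cos(2 pi f t + phi(x))` with `phi(x) = -int_0^x k(s) ds`,
#' so the wave travels toward the apex (increasing `x`). The local phase
#' velocity is `c(x) = 2 pi f / k(x)`.
#'
#' Sound level is converted to peak displacement through a linear-in-pressure
#' calibration: `A_peak = a_ref * 10^((level_db - level_ref_db)/20)`,
#' an order-of-magnitude convention (80 dB SPL maps to 25 nm by default).
#' `active_gain` scales the whole envelope; values below 1 emulate
#' salicylate suppression of outer-hair-cell motility, and 0 silences the
#' wave entirely.
#'
#' @param frequency_khz Stimulus frequency in kHz.
#' @param geometry A [cochlear_geometry()].
#' @param map A [place_frequency_map()]; defaults to the gerbil map rescaled
#'   to `geometry$length_mm`.
#' @param level_db Stimulus level in dB SPL.
#' @param active_gain Dimensionless envelope gain in `[0, 1]`; 1 = fully
#'   active outer hair cells.
#' @param a_ref_nm,level_ref_db Amplitude calibration: peak displacement
#'   `a_ref_nm` (nm) at `level_ref_db` (dB SPL).
#' @param tail_level Envelope height of the basal tail relative to the peak.
#' @param peak_width_mm Gaussian half-width of the envelope peak (mm).
#' @param stall_margin_mm Distance apical of the CF place over which the
#'   envelope is smoothly tapered to exactly zero (mm).
#' @param c_base_mm_s,c_peak_mm_s Phase velocity at the base and at the CF
#'   place (mm/s); `c(x)` interpolates between them with exponent
#'   `c_profile_exp` and stays at `c_peak_mm_s` apical of the peak.
#' @param c_profile_exp Exponent of the phase-velocity decay profile.
#'
#' @return An object of class `c("traveling_wave", "wall_motion_field")`.
#' @examples
#' geo <- cochlear_geometry()
#' wv <- traveling_wave(4.5, geo)
#' wave_profile(wv)
#' @export
traveling_wave <- function(frequency_khz, geometry,
                           map = place_frequency_map(length_mm = geometry$length_mm),
                           level_db = 80, active_gain = 1,
                           a_ref_nm = 25, level_ref_db = 80,
                           tail_level = 0.2, peak_width_mm = 0.4,
                           stall_margin_mm = 0.5,
                           c_base_mm_s = 10000, c_peak_mm_s = 500,
                           c_profile_exp = 2) {
  stop_if_not_scalar_pos(frequency_khz, "frequency_khz")
  stopifnot(inherits(geometry, "cochlear_geometry"))
  stopifnot(is.numeric(active_gain), length(active_gain) == 1L, active_gain >= 0)
  stopifnot(tail_level >= 0, tail_level <= 1)
  stop_if_not_scalar_pos(peak_width_mm, "peak_width_mm")
  stop_if_not_scalar_pos(stall_margin_mm, "stall_margin_mm")
  stopifnot(c_base_mm_s >= c_peak_mm_s, c_peak_mm_s > 0)

  x_peak <- cf_to_place(map, frequency_khz)
  if (x_peak < 0 || x_peak > geometry$length_mm) {
    stop("CF place of the stimulus lies outside the cochlea", call. = FALSE)
  }
  a_peak_um <- active_gain * a_ref_nm * 1e-3 * 10^((level_db - level_ref_db) / 20)

  wave <- new_wall_motion_field(
    f_hz = frequency_khz * 1000,
    a_peak_um = a_peak_um,
    x_peak_mm = x_peak,
    x_max_mm = geometry$length_mm,
    tail_level = tail_level,
    peak_width_mm = peak_width_mm,
    stall_margin_mm = stall_margin_mm,
    c_base_mm_s = c_base_mm_s,
    c_peak_mm_s = c_peak_mm_s,
    c_profile_exp = c_profile_exp,
    standing = FALSE)
  wave$frequency_khz <- frequency_khz
  wave$level_db <- level_db
  wave$active_gain <- active_gain
  class(wave) <- c("traveling_wave", class(wave))
  wave
}

# Shared constructor for parametric wall-motion fields (traveling or
# standing). Phase is integrated once on a fine grid and interpolated.
new_wall_motion_field <- function(f_hz, a_peak_um, x_peak_mm, x_max_mm,
                                  tail_level, peak_width_mm, stall_margin_mm,
                                  c_base_mm_s, c_peak_mm_s, c_profile_exp,
                                  standing = FALSE) {
  x_stall <- x_peak_mm + stall_margin_mm
  omega <- 2 * pi * f_hz

  k_fun <- function(x_mm) {
    # rad/mm; c(x) decays from c_base at x = 0 to c_peak at the CF place
    s <- pmin(pmax(x_mm / x_peak_mm, 0), 1)
    c_mm <- c_peak_mm_s + (c_base_mm_s - c_peak_mm_s) * (1 - s)^c_profile_exp
    omega / c_mm
  }

  amp_fun <- function(x_mm) {
    a <- ifelse(
      x_mm <= x_peak_mm,
      tail_level + (1 - tail_level) *
        exp(-0.5 * ((x_mm - x_peak_mm) / peak_width_mm)^2),
      exp(-0.5 * ((x_mm - x_peak_mm) / peak_width_mm)^2) *
        0.5 * (1 + cos(pi * pmin((x_mm - x_peak_mm) / stall_margin_mm, 1))))
    a[x_mm >= x_stall | x_mm < 0] <- 0
    a_peak_um * a
  }

  xf <- seq(0, x_max_mm, length.out = 4096)
  phi_tab <- -cumtrapz_(xf, k_fun(xf))
  phase_fun <- function(x_mm) {
    approx(xf, phi_tab, xout = pmin(pmax(x_mm, 0), x_max_mm))$y
  }

  structure(
    list(f_hz = f_hz, period_s = 1 / f_hz, a_peak_um = a_peak_um,
         x_peak_mm = x_peak_mm, x_stall_mm = x_stall, x_max_mm = x_max_mm,
         amp_fun = amp_fun, phase_fun = phase_fun, k_fun = k_fun,
         standing = standing),
    class = "wall_motion_field")
}

#' @export
print.wall_motion_field <- function(x, ...) {
  cat(sprintf(
    "<wall_motion_field%s> f = %g Hz, A_peak = %g um at x = %g mm (stall %g mm)\n",
    if (x$standing) ", standing" else "", x$f_hz, x$a_peak_um,
    x$x_peak_mm, x$x_stall_mm))
  invisible(x)
}

#' Amplitude envelope of a wall-motion field
#'
#' @param wave A `wall_motion_field` (e.g. from [traveling_wave()]).
#' @param x_mm Places in mm from the base.
#' @return Envelope displacement amplitude in micrometres, zero apical of the
#'   stall point, maximal (`A_peak`) at the CF place.
#' @export
amplitude_envelope <- function(wave, x_mm) {
  stopifnot(inherits(wave, "wall_motion_field"), is.numeric(x_mm))
  wave$amp_fun(x_mm)
}

#' Phase profile of a wall-motion field
#'
#' `phi(x) = -integral_0^x k(s) ds`: phase lag accumulates apically, so the
#' wave propagates toward the apex with local phase velocity
#' `c(x) = 2 pi f / k(x)`.
#'
#' @inheritParams amplitude_envelope
#' @return Phase in radians (monotone decreasing in `x`).
#' @export
phase_profile <- function(wave, x_mm) {
  stopifnot(inherits(wave, "wall_motion_field"), is.numeric(x_mm))
  wave$phase_fun(x_mm)
}

#' Tabulated wave profile
#'
#' @param wave A `wall_motion_field`.
#' @param x_mm Places at which to tabulate (default: 512 points over the
#'   wave's domain).
#' @return A tibble with columns `x_mm`, `A_um`, `phi_rad`, `k_rad_mm`,
#'   `c_mm_per_s`.
#' @export
wave_profile <- function(wave, x_mm = seq(0, wave$x_max_mm, length.out = 512)) {
  stopifnot(inherits(wave, "wall_motion_field"))
  k <- wave$k_fun(x_mm)
  tibble(x_mm = x_mm,
         A_um = wave$amp_fun(x_mm),
         phi_rad = wave$phase_fun(x_mm),
         k_rad_mm = k,
         c_mm_per_s = 2 * pi * wave$f_hz / k)
}

#' Sample the wall motion at a time point
#'
#' Displacement `A(x) cos(2 pi f t + phi(x))` and its analytic time
#' derivative. For a standing-wave field the spatial phase is frozen into the
#' envelope (`A(x) cos(phi(x)) cos(2 pi f t)`), giving the same local
#' amplitude and wavenumber content but zero phase propagation.
#'
#' @param wave A `wall_motion_field`.
#' @param x_mm Places in mm.
#' @param t_s Time in seconds (`t_s >= 0`).
#' @return A tibble with `x_mm`, `t_s`, `displacement_um`,
#'   `velocity_um_per_s`.
#' @export
wall_motion <- function(wave, x_mm, t_s) {
  stopifnot(inherits(wave, "wall_motion_field"),
            is.numeric(t_s), length(t_s) == 1L, t_s >= 0)
  a <- wave$amp_fun(x_mm)
  ph <- wave$phase_fun(x_mm)
  om <- 2 * pi * wave$f_hz
  if (wave$standing) {
    d <- a * cos(ph) * cos(om * t_s)
    v <- -a * cos(ph) * om * sin(om * t_s)
  } else {
    d <- a * cos(om * t_s + ph)
    v <- -a * om * sin(om * t_s + ph)
  }
  tibble(x_mm = x_mm, t_s = t_s, displacement_um = d, velocity_um_per_s = v)
}

# Wall normal velocity in SI units (m/s) at places x_m (metres), used by the
# flow solver as the deforming-wall boundary condition.
wall_velocity_si <- function(wave, x_m, t_s) {
  a <- wave$amp_fun(x_m * 1000) * 1e-6        # m
  ph <- wave$phase_fun(x_m * 1000)
  om <- 2 * pi * wave$f_hz
  if (wave$standing) {
    -a * cos(ph) * om * sin(om * t_s)
  } else {
    -a * om * sin(om * t_s + ph)
  }
}
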