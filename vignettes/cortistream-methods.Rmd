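---
title: "Sound-driven cochlear fluid streaming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sound-driven cochlear fluid streaming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Inner-ear fluids are classically considered stationary, so a drug placed on
the round window should spread along the cochlea by diffusion alone — taking
tens of minutes per millimetre and effectively never reaching the apex.
`cortistream` models an alternative transport route: sound-evoked,
outer-hair-cell-amplified vibrations deform the organ of Corti (OoC) like a
peristaltic tube. The traveling deformation wave drives a weak but steady
(period-averaged) *streaming* flow — apical along the Corti fluid, returning
basally through the scala tympani — which advects the drug far faster than
diffusion in the wave's tail region. The package implements the three
modelling stages of this hypothesis and the matching neural-recording
analysis chain, plus a seeded synthetic-data generator so every stage is
testable without animal data.

## Stage 1 — the kinematic traveling-wave surrogate

The flow stage only consumes OoC motion as a kinematic boundary condition,
so the full biophysical OoC model is replaced by a parametric surrogate

$$u_m(x,t) = A(x)\,\cos(2\pi f t + \varphi(x)), \qquad
  \varphi(x) = -\int_0^x k(s)\,ds,$$

with an envelope $A(x)$ that rises along a long shallow basal tail
(`tail_level`, default 0.2 of the peak), peaks at the CF place of the
stimulus (Gaussian half-width `peak_width_mm`, default 0.4 mm), and is
cosine-tapered to exactly zero over `stall_margin_mm` (default 0.5 mm)
apical of the peak — the wave "stalls" shortly after its characteristic
place, and a smooth taper avoids a velocity-discontinuity in the wall
boundary condition. The local phase velocity
$c(x) = 2\pi f / k(x)$ decays from `c_base_mm_s` (default 10 m/s) at the
base to `c_peak_mm_s` (default 0.5 m/s) at the peak with a quadratic
profile; phase therefore lags increasingly toward the apex and the wave
propagates apically.

Place and characteristic frequency are linked by a Greenwood-form gerbil map
$\mathrm{CF(kHz)} = 0.398\,(10^{0.022 d} - 0.631)$ with $d$ the percentage
distance from the apex; the map is analytic, monotone and exactly
invertible. Sound level maps to peak displacement through a deliberately
simple linear-in-pressure convention, 25 nm at 80 dB SPL, exposed in
configuration; it is an order-of-magnitude calibration, not a measurement.
`active_gain` multiplies the whole envelope: 1 means fully active outer
hair cells, values below 1 emulate salicylate suppression of
electromotility, and 0 silences the wave.

```{r}
library(cortistream)
geo <- cochlear_geometry()           # 12-mm gerbil duct
wv <- traveling_wave(4.5, geo)       # 4.5-kHz, 80-dB stimulus
wave_profile(wv)
autoplot(wv)
```

## Stage 2 — incompressible flow and the drift field

On the two-layer duct (Corti fluid above, scala tympani below, basilar
membrane between) the package solves the incompressible Navier–Stokes
equations *with the advective term retained*,

$$\partial_t \mathbf u + \mathbf u\cdot\nabla \mathbf u
  = -\tfrac1\rho \nabla p + \nu \nabla^2 \mathbf u,\qquad
  \nabla\cdot\mathbf u = 0,$$

with $\nu = 70\times10^{-6}\,\mathrm{m^2/s}$ (one hundred times water,
representing the flow resistance of the OoC microstructure; applied in both
layers) and $\rho = 1000\,\mathrm{kg/m^3}$. The advective term is exactly
what generates steady streaming: the time-periodic first-order flow has
spatially varying phase, so $\overline{\mathbf u \cdot \nabla \mathbf u}$
does not vanish and drives a secondary steady circulation. The drift field
is the period average of the Eulerian velocity,
$\mathbf u_D(\mathbf x) = \frac1T\int_t^{t+T}\mathbf u_E\,d\tau$ —
second order in the wall amplitude, hence the exact quadratic
amplitude-scaling law used as a solver check.

Boundary conditions: no slip on rigid walls; on the deforming top wall the
normal velocity $\partial_t u_m$ is prescribed at the mean wall position
(amplitudes of nanometres to micrometres against a 60-µm layer justify the
linearised wall) with zero tangential slip. The basilar membrane is a
Darcy interface: the transmembrane fluid velocity is
$u_p = -K\,\Delta p$ with $K = 1\,\mathrm{m/(s\,Pa)}$, composed with the
membrane's own motion as $u_f = u_m + u_p$; tangentially the membrane is
no-slip on both sides. Drift results change by well under 20% when $K$
varies over an order of magnitude (an explicit regression test), so the
empirical value is uncritical. With $K=0$ the interface degenerates to an
impermeable wall and the pressure system splits into two independently
gauged layers.

One well-posedness subtlety: a prescribed deforming wall on an otherwise
closed box injects a small oscillatory net volume flux, which is
incompatible with exact incompressibility. The prescribed wall velocity is
therefore *volume-compensated* — its instantaneous spatial mean is
subtracted — which acts as a surrogate for round-window compliance. For a
traveling wave spanning several wavelengths the compensation is a small
correction (the phase-varying integrand largely cancels).

**Discretisation.** Uniform staggered marker-and-cell grid; Crank–Nicolson
viscous terms; second-order Adams–Bashforth central-difference advection; a
pressure projection enforcing the discrete continuity equation after every
step, with the Darcy law built directly into the projection matrix (the
membrane face velocity is eliminated in favour of the adjacent pressures,
keeping the system symmetric positive definite). All three implicit
operators are factorised once per run (sparse Cholesky). Grid cells satisfy
$\Delta y \le \tfrac13\sqrt{\nu/\omega}$ (boundary-layer resolution rule —
at 1 kHz the oscillatory boundary layer is ≈150 µm, so 10–15-µm cells are
comfortable) and the period is resolved by at least 100 steps (120 by
default; the reference full-scale step of 10 µs at 1 kHz corresponds to
100). The wall forcing is ramped up smoothly over the first three cycles so
the startup transient (which decays on the fast viscous time scale
$h^2/\pi^2\nu \approx 0.4$ ms) does not contaminate the period average, and
integration continues until the relative L2 change between consecutive
cycle-averaged velocity fields falls below `tol_periodic` (default
$10^{-3}$; the acceptance runs use $10^{-4}$). Non-convergence is flagged,
never silent. Correctness is anchored by two closed-form benchmarks run in
an x-periodic channel: plane Poiseuille flow (observed convergence order
2.0) and Stokes' oscillating-plate flow
($u = U_0 e^{-y/\delta}\cos(\omega t - y/\delta)$,
$\delta = \sqrt{2\nu/\omega}$; L2 error ≈0.1%).

**Desk scale.** The demonstration domain is a 3-mm truncation of the duct
(the wave's active span plus margins) at 25 × 12 µm resolution
(120 × 45 cells), 60-µm Corti fluid over 480-µm scala, 1-kHz stimulus with
the envelope peaking at 2.2 mm — one periodic-steady-state run takes a few
seconds. Full-resolution settings remain plain configuration.

**Interpreting the drift field.** For an apically traveling wave the
period-averaged flow streams apically along the Corti layer over the wave's
span and returns basally through the scala. Two measurement conventions
matter and are deliberate:

* "along the bottom of the scala tympani" is measured as the mean axial
  drift over the *lower half* of the scala layer. Within one oscillatory
  boundary-layer thickness of the rigid floor the drift necessarily decays
  to zero (with weak near-wall streaming cells), so the single bottom-most
  cell row is not representative of the return stream, which occupies the
  scala interior.
* The standing-wave control (same envelope and local wavenumber content,
  spatial phase frozen: $A(x)\cos\varphi(x)\cos\omega t$) is *not* a zero
  of streaming: oscillatory flows with strong envelope gradients generate
  classical Rayleigh streaming cells of comparable local magnitude. What
  phase propagation adds is *directional transport*: the traveling wave
  strictly exceeds the standing wave both in peak streaming magnitude and
  in directional Corti-layer drift, and the stationary-wall case is exactly
  zero. The package asserts those orderings rather than an arbitrary small
  fraction.

The kinematic surrogate at the 25-nm calibration produces drift of order
$10^{-4}$ µm/s — far weaker than a full active-OoC model, whose effective
peristaltic deformation is much larger. The mechanism and facilitation
demonstrations therefore use a 4-µm fixture wave, which puts the tail-region
advective Péclet number near unity (tail-line drift 0.5–5 µm/s); direction
and scaling properties are amplitude-independent, as the exact quadratic
scaling shows.

## Stage 3 — advection–diffusion transport and effect times

Drug concentration obeys
$\partial_t C = D\nabla^2 C - \mathbf u_D\cdot\nabla C$ with the converged
drift field held constant over the minutes-long transport horizon
(quasi-steady coupling: the acoustic period and the transport time scale are
five orders of magnitude apart). The round-window patch (default: the basal
0.2 mm of the scala floor) is held at $C_0 = 10$ mM; all other exterior
boundaries are zero-flux; the membrane is open to both diffusive exchange
(same $D$) and advective Darcy flux. The kainic-acid diffusivity is not a
measured value; the default $D = 8\times10^{-10}\,\mathrm{m^2/s}$ is the
small-molecule scale, and every oracle is parameterised in $D$. A location's
*effect time* $t_E$ is when its concentration first reaches
$f_{thr} C_0$ (1%, i.e. 100 µM), linearly interpolated between recorded
times, on an observation line at Corti-fluid mid-height (the inner-hair-cell
row surrogate; configurable).

**Discretisation.** Conservative finite volumes on the flow grid; implicit
backward-Euler diffusion (L-stable and monotone, so the discrete maximum
principle $0\le C\le C_0$ holds to round-off — Crank–Nicolson was rejected
here because at Fourier numbers of order $10^2$ it oscillates at steep
fronts); explicit donor-cell advection. At the model's grid Péclet numbers
($u\,\Delta x/2D \lesssim 0.02$) the upwind truncation diffusivity is
negligible against $D$, which is why no flux limiter is needed. The time
step starts at one wave period (1 ms) and grows on a geometric ladder
(×1.25 per level, so implicit factorisations are reused within a level),
capped at 4% of elapsed time — a temporal-accuracy control that keeps the
backward-Euler error in $t_E$ well under the 5% oracle tolerance — and at
an advective CFL of 0.4. The mass budget (interior change versus boundary
influx, both evaluated with the same discrete fluxes, the diffusive part at
the implicit end-of-step state) closes to round-off, a much stronger check
than the 0.1% contract.

Two comparison conventions: the silence-case oracle
$t_E = x^2 / (4 D\,[\mathrm{erfc}^{-1}(f_{thr})]^2)$ is evaluated with $x$
measured from the discrete Dirichlet plane (the pinned cell centre), the
correct continuum limit of a cell-pinned boundary; and the facilitation
contract ("drift strictly shortens $t_E$") is asserted on the wave's
*fast-track* window, $0.6$–$0.95\,x_{peak}$. Basal of that window the
simulated return current along the scala floor sweeps low-concentration
fluid toward the source and mildly *delays* delivery on the observation
line — the same circulation that stretches concentration contours apically
in the Corti layer and basally near the scala floor. With `active_gain = 0`
(salicylate emulation) the wall is silent, the drift vanishes identically,
and the advection operator annihilates exactly, so the effect-time map
coincides with the silence case to machine precision.

## The measurement-analysis chain

The experimental pipeline is implemented as tibble-first verbs:

* `teager_energy()` — $\Psi[n] = x[n]^2 - x[n-1]x[n+1]$; for a sinusoid
  $\Psi \equiv A^2\sin^2\Omega$, phase-free (identity tested to $10^{-10}$).
* `segment_responses()` — per-segment mean Teager amplitude along the
  57.2-s stimulus sequence (48 noise pips + 1 pause + 3 CF-tone pips,
  1.1 s each); incomplete trailing sequences are dropped with a warning.
* `driven_response_curve()` — per sequence, CF-tone minus pause (driven
  response), normalised by the mean over all pre-application sequences.
  An optional centred 3-sequence moving average is available but off by
  default.
* `effect_time()` — first *sustained* (≥2 consecutive sequences) downward
  crossing of 75% of baseline, linearly interpolated; curves that re-rise
  above criterion by >0.1 afterwards are flagged bimodal, never-crossing
  curves are flagged and carry no number.
* `fit_diffusion_trend()` — least squares of $\log t_E$ on the
  one-parameter model $t = a x^2$ (log-space residuals match the dB scale
  used throughout); the threshold fraction inside
  $\beta = \mathrm{erfc}^{-1}(f_{thr})$ is not separately identifiable from
  $(x, t_E)$ data and is fixed by configuration when converting $a$ to an
  effective diffusivity.
* `effect_time_db()` — $20\log_{10}(t_E/t_{Trend})$, exactly invertible.
* `compare_groups()` — two-tailed Welch t-test (the unequal-variance form
  is the safe default for unbalanced animal groups) with per-group means
  and 95% confidence intervals.
* `dpoae_level_sweep()` — least-squares sinusoid fit at the instantaneous
  $2f_1-f_2$ frequency in a 100-ms Hann window stepped by 20 ms along the
  linear $f_2$ sweep ($f_2 = 1.25 f_1$, 0.5→10 kHz in 4 s); the noise floor
  is the identical analysis of the even-minus-odd presentation difference.

## The synthetic-data generator

`synth_recording()` emulates the recording protocol: white-noise spontaneous
activity; per-channel CF-tone responses whose *Teager power* decays as a
logistic $g(t) = [1+e^{(t - t_{mid})/\tau}]^{-1}$ calibrated so the
normalised curve crosses 0.75 exactly at the ground-truth $t_E$
($t_{mid} = t_E + \tau\ln 3$, $\tau = 1$ min); broadband driven energy in
the noise pips (unused by the analysis, kept for realism); independent
per-segment level jitter; and an optional rebound mode that exercises the
bimodal flag. Amplitudes are set in Teager-power units via the sinusoid
identity, so the driven-to-spontaneous ratio (default 5) is exact by
construction.

Desk-scale defaults: 4-kHz sampling with apical CFs (1.5/0.9/0.5 kHz),
ground-truth effect times of 3/5/8 min (the faster end of observed in-vivo
decays), 4 baseline sequences (≈3.8 min — the published example records
show several minutes of pre-application baseline, and a shorter baseline
makes the normalisation itself the dominant error source) and 12
post-application sequences. Per-segment jitter defaults to 0.25 dB, giving
≈5% point-to-point scatter on the normalised curve — visibly noisy,
comparable to published example curves — under which the crossing estimator
recovers $t_E$ within one sequence duration essentially always; at twice
that jitter the 75% criterion begins to trigger early on noise dips in the
logistic shoulder, which is worth knowing when applying the chain to real
data. What the generator does *not* emulate: spike waveforms and
refractoriness, tuning-curve selectivity (channels respond only to their
own CF tone), slow electrode drift, and the post-salicylate probe-level
re-baselining of real experiments. Passing tests therefore validate the
*analysis chain*, not the biology of real recordings.

All stochastic outputs run under an explicit seed through R's default
Mersenne-Twister stream, restore the caller's RNG state, and are
byte-reproducible.

## Worked example

```{r}
geo <- cochlear_geometry(length_mm = 3, corti_height_um = 60,
                         scala_height_um = 480, dx_um = 25)
grid <- flow_grid(geo, dy_um = 12)
sol <- run_periodic(flow_problem(grid, wall = synth_wall_motion(), dt_s = 1e-5))
drift_summary(sol, c(1.3, 2.1))
autoplot(sol)

cfg <- transport_config(horizon_min = 20)
silence <- run_delivery(grid, cfg)
sound <- run_delivery(grid, cfg, drift = sol)
library(dplyr)
left_join(effect_time_map(silence), effect_time_map(sound),
          by = "x_mm", suffix = c("_silence", "_sound"))
```

## Known limitations

* One-way coupling: the wave shapes the flow and the flow never feeds back;
  compressive cochlear nonlinearity is not represented (salicylate is a
  pure envelope gain).
* Two rectangular layers only — no scala vestibuli/media, no coiling, no
  tapering; end walls are rigid (volume compensation stands in for window
  compliance).
* The drift magnitude depends quadratically on an amplitude calibration
  that is an order-of-magnitude convention; only directions, scalings and
  paired contrasts should be read quantitatively.
* Transport has no clearance, binding, or electrochemical homeostasis;
  the membrane's solute permeability is idealised as free exchange at the
  fluid diffusivity.
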