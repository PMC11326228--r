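#' Transport configuration for intracochlear drug delivery
#'
#' Parameters of the advection-diffusion stage: the drug is held at a fixed
#' concentration `C0_mM` on a round-window patch, diffuses with coefficient
#' `D_m2_s`, is advected by the (quasi-steady) drift field, and a location is
#' counted as "affected" when its concentration first reaches the fraction
#' `f_thr` of the round-window concentration (1% of 10 mM = 100 uM by
#' default).
#'
#' Time stepping is adaptive: the step starts at `dt0_s` (one wave period)
#' and grows geometrically by `dt_growth` per level, capped at
#' `dt_max_frac` times the elapsed time (temporal-accuracy control of the
#' implicit diffusion step) and at the advective CFL limit `cfl`.
#'
#' @param D_m2_s Diffusion coefficient, m^2/s (kainic-acid scale 8e-10).
#' @param C0_mM Round-window concentration, mM.
#' @param f_thr Effect-threshold fraction of `C0_mM`, in (0, 1).
#' @param patch `"scala_bottom"` (Dirichlet patch on the basal
#'   `patch_extent_mm` of the scala-tympani floor) or `"basal_wall"` (whole
#'   basal cross-section held at `C0`; gives an exactly one-dimensional
#'   diffusion problem in the silence case).
#' @param patch_extent_mm Axial extent of the scala-bottom patch, mm.
#' @param horizon_min Simulation horizon, minutes.
#' @param obs_line Observation line for the effect-time map:
#'   `"corti_mid"` (Corti-fluid mid-height, the inner-hair-cell row
#'   surrogate) or `"scala_mid"`.
#' @param dt0_s,dt_growth,dt_max_frac,cfl Time-step controls (see
#'   Description).
#' @param n_snapshots Number of full concentration snapshots kept (log-spaced
#'   in time); the observation line is recorded at every step regardless.
#' @return A `transport_config` object.
#' @export
transport_config <- function(D_m2_s = 8e-10, C0_mM = 10, f_thr = 0.01,
                             patch = c("scala_bottom", "basal_wall"),
                             patch_extent_mm = 0.2, horizon_min = 30,
                             obs_line = c("corti_mid", "scala_mid"),
                             dt0_s = 1e-3, dt_growth = 1.25,
                             dt_max_frac = 0.04, cfl = 0.4,
                             n_snapshots = 8) {
  stop_if_not_scalar_pos(D_m2_s, "D_m2_s")
  stop_if_not_scalar_pos(C0_mM, "C0_mM")
  stopifnot(f_thr > 0, f_thr < 1)
  structure(
    list(D = D_m2_s, C0 = C0_mM, f_thr = f_thr,
         patch = match.arg(patch), patch_extent_mm = patch_extent_mm,
         horizon_min = horizon_min, obs_line = match.arg(obs_line),
         dt0 = dt0_s, dt_growth = dt_growth, dt_max_frac = dt_max_frac,
         cfl = cfl, n_snapshots = n_snapshots),
    class = "transport_config")
}

# logical patch mask over cells (nx x ny)
patch_mask <- function(g, config) {
  m <- matrix(FALSE, g$nx, g$ny)
  if (config$patch == "basal_wall") {
    m[1, ] <- TRUE
  } else {
    if (is.na(g$j_mem)) {
      m[g$x_c * 1000 <= config$patch_extent_mm, 1] <- TRUE
    } else {
      m[g$x_c * 1000 <= config$patch_extent_mm, 1] <- TRUE
    }
  }
  m
}

# cell-centred diffusion Laplacian (zero-flux exterior walls, membrane open
# to diffusion with the same D), as links between all cells
build_Ld <- function(g, D) {
  nx <- g$nx; ny <- g$ny
  idx <- function(i, j) i + (j - 1L) * nx
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b)
    vv <<- c(vv, rep_len(v, length(a)))
  }
  ax <- D / g$dx^2; ay <- D / g$dy^2
  I <- rep(seq_len(nx), ny); J <- rep(seq_len(ny), each = nx)
  ctr <- idx(I, J)
  w <- I > 1L;  add(ctr[w], idx(I[w] - 1L, J[w]), ax); add(ctr[w], ctr[w], -ax)
  w <- I < nx;  add(ctr[w], idx(I[w] + 1L, J[w]), ax); add(ctr[w], ctr[w], -ax)
  w <- J > 1L;  add(ctr[w], idx(I[w], J[w] - 1L), ay); add(ctr[w], ctr[w], -ay)
  w <- J < ny;  add(ctr[w], idx(I[w], J[w] + 1L), ay); add(ctr[w], ctr[w], -ay)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * ny, nx * ny))
}

# donor-cell advective increment; returns list(dC, influx) where influx is
# the advective mass flow into free cells from patch cells (per unit time).
# At the grid Peclet numbers of this model (u dx / 2 D << 1) the upwind
# truncation diffusivity is negligible against D.
adv_increment <- function(C, uf, vf, g) {
  nx <- g$nx; ny <- g$ny
  # x faces (interior i = 2..nx)
  Fx <- matrix(0, nx + 1L, ny)
  up <- pmax(uf[2:nx, , drop = FALSE], 0); un <- pmin(uf[2:nx, , drop = FALSE], 0)
  Fx[2:nx, ] <- up * C[1:(nx - 1), , drop = FALSE] + un * C[2:nx, , drop = FALSE]
  # y faces (interior j = 2..ny, includes the membrane face flux u_p C)
  Fy <- matrix(0, nx, ny + 1L)
  vp <- pmax(vf[, 2:ny, drop = FALSE], 0); vn <- pmin(vf[, 2:ny, drop = FALSE], 0)
  Fy[, 2:ny] <- vp * C[, 1:(ny - 1), drop = FALSE] + vn * C[, 2:ny, drop = FALSE]
  dC <- -((Fx[2:(nx + 1), , drop = FALSE] - Fx[1:nx, , drop = FALSE]) / g$dx +
          (Fy[, 2:(ny + 1), drop = FALSE] - Fy[, 1:ny, drop = FALSE]) / g$dy)
  list(dC = dC, Fx = Fx, Fy = Fy)
}

#' One conservative advection-diffusion step
#'
#' Explicit donor-cell advection by the drift field followed by an implicit
#' (backward Euler) diffusion solve; Dirichlet cells in `patch` are held at
#' `config$C0`. Intended for testing and small problems; [run_delivery()]
#' uses a cached-factorisation fast path of the same discretisation.
#'
#' @param C Concentration matrix (`nx x ny`, mM).
#' @param grid A [flow_grid()] (or [channel_grid()]).
#' @param config A [transport_config()].
#' @param dt_s Time step, s.
#' @param drift A `flow_solution` on the same grid, or `NULL` for pure
#'   diffusion.
#' @param patch Logical `nx x ny` mask of fixed-concentration cells;
#'   default from `config`.
#' @return The updated concentration matrix.
#' @export
advance_concentration <- function(C, grid, config, dt_s, drift = NULL,
                                  patch = patch_mask(grid, config)) {
  g <- grid
  stopifnot(is.matrix(C), nrow(C) == g$nx, ncol(C) == g$ny)
  fv <- drift_faces(drift, g)
  cflx <- max(abs(fv$uf)) * dt_s / g$dx + max(abs(fv$vf)) * dt_s / g$dy
  if (cflx > 1) {
    iworst <- which.max(abs(fv$uf))
    stop(sprintf(
      "advective CFL %.2f > 1 at dt = %g s (limiting u-face index %d); reduce dt",
      cflx, dt_s, iworst), call. = FALSE)
  }
  adv <- adv_increment(C, fv$uf, fv$vf, g)
  C1 <- C + dt_s * adv$dC
  C1[patch] <- config$C0
  Ld <- build_Ld(g, config$D)
  free <- which(!patch)
  fixed <- which(patch)
  A <- Matrix::Diagonal(length(free)) - dt_s * Ld[free, free, drop = FALSE]
  b <- as.vector(C1)[free]
  if (length(fixed)) {
    b <- b + dt_s * as.numeric(Ld[free, fixed, drop = FALSE] %*%
                                 rep(config$C0, length(fixed)))
  }
  out <- C1
  out[free] <- as.numeric(Matrix::solve(A, b))
  out[fixed] <- config$C0
  out
}

# face drift velocities from a flow solution (or zeros); requires matching
# grids
drift_faces <- function(drift, g) {
  if (is.null(drift)) {
    return(list(uf = matrix(0, g$nx + 1L, g$ny), vf = matrix(0, g$nx, g$ny + 1L)))
  }
  stopifnot(inherits(drift, "flow_solution"))
  if (!identical(dim(drift$u_drift), c(g$nx + 1L, g$ny))) {
    stop("drift field grid does not match the transport grid", call. = FALSE)
  }
  uf <- drift$u_drift
  vf <- drift$v_drift
  # enforce exactly closed exterior boundaries (cycle-average roundoff)
  uf[1, ] <- 0; uf[g$nx + 1L, ] <- 0
  vf[, 1] <- 0; vf[, g$ny + 1L] <- 0
  list(uf = uf, vf = vf)
}

#' Simulate drug delivery and effect times
#'
#' Integrates the advection-diffusion equation for the drug concentration on
#' the two-layer domain to the horizon, with the round-window patch held at
#' `C0`, zero-flux exterior walls, and the basilar membrane open to both
#' diffusive and advective (Darcy drift) exchange. The silence case
#' (`drift = NULL`) reduces exactly to pure diffusion: the advection operator
#' contributes identically zero.
#'
#' @param grid A [flow_grid()].
#' @param config A [transport_config()].
#' @param drift A converged `flow_solution` on the same grid, or `NULL`.
#' @return A `delivery_run` with the observation-line concentration history,
#'   log-spaced snapshots, mass-budget diagnostics, and extrema tracking.
#' @export
run_delivery <- function(grid, config = transport_config(), drift = NULL) {
  g <- grid
  stopifnot(inherits(config, "transport_config"))
  fv <- drift_faces(drift, g)
  patch <- patch_mask(g, config)
  free <- which(!patch); fixed <- which(patch)
  Ld <- build_Ld(g, config$D)
  Lff <- Ld[free, free, drop = FALSE]
  Lfp <- if (length(fixed)) Ld[free, fixed, drop = FALSE] else NULL
  bp <- if (!is.null(Lfp)) as.numeric(Lfp %*% rep(config$C0, length(fixed))) else NULL
  rSfp <- if (!is.null(Lfp)) Matrix::rowSums(Lfp) else NULL
  j_obs <- if (config$obs_line == "corti_mid" && !is.na(g$j_mem)) {
    g$ny_s + max(1L, ceiling(g$ny_c / 2))
  } else {
    max(1L, ceiling(g$ny_s / 2))
  }
  horizon <- config$horizon_min * 60
  dt_cfl <- if (max(abs(fv$uf)) + max(abs(fv$vf)) > 0) {
    config$cfl / (max(abs(fv$uf)) / g$dx + max(abs(fv$vf)) / g$dy)
  } else Inf

  C <- matrix(0, g$nx, g$ny)
  C[fixed] <- config$C0
  t <- 0
  level <- 0L
  fac_cache <- list()
  times <- numeric(0)
  line <- NULL
  lines <- list()
  snap_times <- exp(seq(log(max(10 * config$dt0, 1)), log(horizon),
                        length.out = config$n_snapshots))
  snaps <- list(); snap_t <- numeric(0)
  mass_in <- 0
  mass0 <- sum(C[free]) * g$dx * g$dy
  cmin <- 0; cmax <- config$C0
  step <- 0L
  times <- c(times, 0); lines[[1]] <- C[, j_obs]
  repeat {
    if (t >= horizon) break
    # adaptive step level: largest allowed dt on the geometric ladder
    repeat {
      dt_next <- config$dt0 * config$dt_growth^(level + 1L)
      if (dt_next <= max(config$dt_max_frac * t, config$dt0) &&
          dt_next <= dt_cfl) level <- level + 1L else break
    }
    dt <- min(config$dt0 * config$dt_growth^level, horizon - t)
    key <- sprintf("%.6g", dt)
    if (is.null(fac_cache[[key]])) {
      A <- Matrix::Diagonal(length(free)) - dt * Lff
      fac_cache[[key]] <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"))
    }
    adv <- adv_increment(C, fv$uf, fv$vf, g)
    # advective influx from patch cells into free cells (for the budget)
    adv_in <- advective_patch_influx(adv, patch, g)
    C1 <- C + dt * adv$dC
    C1[fixed] <- config$C0
    b <- as.vector(C1)[free]
    if (!is.null(bp)) b <- b + dt * bp
    sol <- as.numeric(Matrix::solve(fac_cache[[key]], b, system = "A"))
    Cn <- C1
    Cn[free] <- sol
    Cn[fixed] <- config$C0
    # diffusive influx through patch faces, evaluated at the backward-Euler
    # end-of-step concentrations (exactly consistent with the discrete
    # update): sum over patch-free faces of D (C0 - C_free^{n+1}) / dh
    diff_in <- if (!is.null(bp)) {
      (sum(bp) - sum(rSfp * sol)) * g$dx * g$dy
    } else 0
    mass_in <- mass_in + dt * (diff_in + adv_in)
    C <- Cn
    t <- t + dt
    step <- step + 1L
    cmin <- min(cmin, min(C)); cmax <- max(cmax, max(C))
    times <- c(times, t)
    lines[[length(lines) + 1L]] <- C[, j_obs]
    if (length(snap_t) < length(snap_times) &&
        t >= snap_times[length(snap_t) + 1L]) {
      snaps[[length(snaps) + 1L]] <- C
      snap_t <- c(snap_t, t)
    }
  }
  line <- do.call(rbind, lines)
  mass_end <- sum(C[free]) * g$dx * g$dy
  budget_err <- abs((mass_end - mass0) - mass_in) /
    max(abs(mass_end - mass0), .Machine$double.xmin)
  structure(
    list(grid = g, config = config, with_drift = !is.null(drift),
         times_s = times, line = line, j_obs = j_obs,
         snapshots = snaps, snapshot_times_s = snap_t,
         mass_in = mass_in, mass_change = mass_end - mass0,
         budget_rel_err = budget_err,
         c_min = cmin, c_max = cmax, n_steps = step,
         final = C),
    class = "delivery_run")
}

# advective mass inflow rate from patch cells to free cells
advective_patch_influx <- function(adv, patch, g) {
  nx <- g$nx; ny <- g$ny
  infl <- 0
  # x faces between (i-1, j) and (i, j), i = 2..nx
  pl <- patch[1:(nx - 1), , drop = FALSE]; pr <- patch[2:nx, , drop = FALSE]
  fx <- adv$Fx[2:nx, , drop = FALSE]
  infl <- infl + sum(fx[pl & !pr]) * g$dy       # into right cell
  infl <- infl - sum(fx[!pl & pr]) * g$dy       # out of left free cell? no:
  # flux Fx > 0 moves mass +x: from cell (i-1) into (i). If left is patch and
  # right is free, free gains +Fx*dy; if left free and right patch, free
  # loses +Fx*dy (counted as negative influx).
  py <- patch[, 1:(ny - 1), drop = FALSE]; pu <- patch[, 2:ny, drop = FALSE]
  fy <- adv$Fy[, 2:ny, drop = FALSE]
  infl <- infl + sum(fy[py & !pu]) * g$dx
  infl <- infl - sum(fy[!py & pu]) * g$dx
  infl
}

#' @export
print.delivery_run <- function(x, ...) {
  cat(sprintf(
    "<delivery_run> %s, %d steps to %0.3g min; mass budget %.2g; C in [%0.3g, %0.3g] mM\n",
    if (x$with_drift) "with drift" else "pure diffusion", x$n_steps,
    max(x$times_s) / 60, x$budget_rel_err, x$c_min, x$c_max))
  invisible(x)
}

#' Tidy the observation-line history of a delivery run
#'
#' @param x A `delivery_run`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `x_mm`, `conc_mM` on the observation line.
#' @export
tidy.delivery_run <- function(x, ...) {
  g <- x$grid
  tibble(
    time_s = rep(x$times_s, times = g$nx),
    x_mm = rep(g$x_c * 1000, each = length(x$times_s)),
    conc_mM = as.vector(x$line))
}

#' @export
glance.delivery_run <- function(x, ...) {
  tibble(n_steps = x$n_steps, t_end_min = max(x$times_s) / 60,
         with_drift = x$with_drift, budget_rel_err = x$budget_rel_err,
         c_min = x$c_min, c_max = x$c_max)
}

#' Effect-time map from a concentration history
#'
#' The effect time of a location is the first time its concentration reaches
#' `f_thr * C0` (100 uM by default), linearly interpolated between recorded
#' times. Locations that never reach threshold within the horizon are
#' flagged (`reached = FALSE`, `t_e_min = NA`).
#'
#' @param x A `delivery_run`, or a data frame with columns `time_s`, `x_mm`,
#'   `conc_mM`.
#' @param config A [transport_config()] (supplies `f_thr` and `C0`);
#'   defaults to the run's own config.
#' @return Tibble with `x_mm`, `t_e_min`, `reached`.
#' @export
effect_time_map <- function(x, config = NULL) {
  if (inherits(x, "delivery_run")) {
    cfg <- if (is.null(config)) x$config else config
    times <- x$times_s
    mat <- x$line
    xs <- x$grid$x_c * 1000
  } else {
    if (is.null(config)) stop("`config` is required for a raw history", call. = FALSE)
    cfg <- config
    df <- as_tibble(x)
    stopifnot(all(c("time_s", "x_mm", "conc_mM") %in% names(df)))
    if (nrow(df) == 0) stop("empty history", call. = FALSE)
    xs <- sort(unique(df$x_mm))
    times <- sort(unique(df$time_s))
    mat <- matrix(NA_real_, length(times), length(xs))
    mat[cbind(match(df$time_s, times), match(df$x_mm, xs))] <- df$conc_mM
  }
  if (length(times) < 2) stop("history needs at least two time points", call. = FALSE)
  thr <- cfg$f_thr * cfg$C0
  te <- vapply(seq_along(xs), function(i) {
    ci <- mat[, i]
    k <- which(ci >= thr)
    if (!length(k)) return(NA_real_)
    k1 <- k[1]
    if (k1 == 1) return(times[1])
    t0 <- times[k1 - 1]; t1 <- times[k1]
    c0 <- ci[k1 - 1]; c1 <- ci[k1]
    t0 + (thr - c0) / (c1 - c0) * (t1 - t0)
  }, numeric(1))
  tibble(x_mm = xs, t_e_min = te / 60, reached = !is.na(te))
}

#' Closed-form effect time for one-dimensional diffusion
#'
#' For pure diffusion from a plane held at `C0`, the concentration is
#' `C(x, t) = C0 erfc(x / (2 sqrt(D t)))`, so the time to reach the fraction
#' `f_thr` at distance `x` is `t_E = x^2 / (4 D erfcinv(f_thr)^2)`.
#'
#' @param x_mm Distance from the source plane, mm.
#' @param D_m2_s Diffusion coefficient, m^2/s.
#' @param f_thr Threshold fraction in (0, 1).
#' @return Effect time in minutes.
#' @examples
#' diffusion_effect_time(1)   # ~1.6 min at kainic-acid scale
#' @export
diffusion_effect_time <- function(x_mm, D_m2_s = 8e-10, f_thr = 0.01) {
  beta <- erfcinv_(f_thr)
  (x_mm * 1e-3)^2 / (4 * D_m2_s * beta^2) / 60
}
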