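#' Fluid properties of the cochlear fluids
#'
#' The effective kinematic viscosity of the Corti/scala fluids is taken as one
#' hundred times that of water, reflecting the flow resistance of the
#' cellular microstructure in the radially reduced 2-D duct.
#'
#' @param nu_m2_s Kinematic viscosity in m^2/s.
#' @param rho_kg_m3 Density in kg/m^3.
#' @return A `fluid_properties` object.
#' @export
fluid_properties <- function(nu_m2_s = 70e-6, rho_kg_m3 = 1000) {
  stop_if_not_scalar_pos(nu_m2_s, "nu_m2_s")
  stop_if_not_scalar_pos(rho_kg_m3, "rho_kg_m3")
  structure(list(nu = nu_m2_s, rho = rho_kg_m3), class = "fluid_properties")
}

#' Darcy model of the basilar membrane
#'
#' The fluid velocity through the membrane is proportional to the
#' transmembrane pressure difference, `u_p = -K * (p_above - p_below)`.
#' `K = 0` degenerates to an impermeable wall. The default `K = 1 m/(s Pa)`
#' keeps Corti-fluid pressures below a few pascals; drift results are
#' insensitive to `K` over at least an order of magnitude.
#'
#' @param K_m_s_pa Permeability coefficient in m/(s Pa); must be `>= 0`.
#' @return A `membrane_model` object.
#' @export
membrane_model <- function(K_m_s_pa = 1) {
  if (!is.numeric(K_m_s_pa) || length(K_m_s_pa) != 1L || K_m_s_pa < 0) {
    stop("`K_m_s_pa` must be a single non-negative number", call. = FALSE)
  }
  structure(list(K = K_m_s_pa), class = "membrane_model")
}

#' Darcy velocity through the basilar membrane
#'
#' @param p_above,p_below Pressure on the Corti-fluid (above) and
#'   scala-tympani (below) side, Pa.
#' @param K Permeability in m/(s Pa), `K >= 0`.
#' @param u_m Membrane (solid) velocity in m/s; the fluid velocity at the
#'   membrane is `u_f = u_m + u_p`.
#' @return A list with `u_p` (Darcy flux) and `u_f` (composed fluid velocity).
#' @examples
#' membrane_velocity(2, 0, K = 1)   # u_p = -2 m/s
#' @export
membrane_velocity <- function(p_above, p_below, K = 1, u_m = 0) {
  if (any(K < 0)) stop("`K` must be non-negative", call. = FALSE)
  u_p <- -K * (p_above - p_below)
  list(u_p = u_p, u_f = u_m + u_p)
}

#' Staggered two-layer grid for the flow solver
#'
#' Builds a uniform marker-and-cell grid over the two stacked fluid layers of
#' a [cochlear_geometry()], with the membrane interface coinciding with a row
#' of vertical-velocity faces. `dy_um` must divide both layer heights.
#'
#' @param geometry A [cochlear_geometry()].
#' @param dy_um Vertical grid spacing in micrometres. Should not exceed a
#'   third of the oscillatory boundary-layer thickness `sqrt(nu/omega)`.
#' @return A `flow_grid` object.
#' @export
flow_grid <- function(geometry, dy_um = 12) {
  stopifnot(inherits(geometry, "cochlear_geometry"))
  stop_if_not_scalar_pos(dy_um, "dy_um")
  ny_c <- geometry$corti_height_um / dy_um
  ny_s <- geometry$scala_height_um / dy_um
  if (abs(ny_c - round(ny_c)) > 1e-9 || abs(ny_s - round(ny_s)) > 1e-9) {
    stop("`dy_um` must divide both layer heights", call. = FALSE)
  }
  new_flow_grid(nx = geometry$nx, ny_s = as.integer(round(ny_s)),
                ny_c = as.integer(round(ny_c)),
                dx = geometry$dx_um * 1e-6, dy = dy_um * 1e-6)
}

#' Single-layer channel grid (for solver verification)
#'
#' A rectangular closed channel without a membrane, used for analytic
#' benchmark flows (plane Poiseuille flow, Stokes' oscillating-plate flow).
#'
#' @param length_mm,height_um Channel dimensions.
#' @param dx_um,dy_um Grid spacings in micrometres.
#' @param periodic Make the channel periodic in `x` (no side walls); used by
#'   the x-invariant benchmark flows.
#' @return A `flow_grid` object with no membrane.
#' @export
channel_grid <- function(length_mm, height_um, dx_um, dy_um, periodic = FALSE) {
  nx <- round(length_mm * 1000 / dx_um)
  ny <- round(height_um / dy_um)
  new_flow_grid(nx = as.integer(nx), ny_s = as.integer(ny), ny_c = 0L,
                dx = dx_um * 1e-6, dy = dy_um * 1e-6, periodic = periodic)
}

new_flow_grid <- function(nx, ny_s, ny_c, dx, dy, periodic = FALSE) {
  ny <- ny_s + ny_c
  structure(
    list(nx = nx, ny = ny, ny_s = ny_s, ny_c = ny_c, periodic = periodic,
         dx = dx, dy = dy, Lx = nx * dx, Ly = ny * dy,
         # v-face row index of the membrane (1 = bottom wall, ny+1 = top wall)
         j_mem = if (ny_c > 0L) ny_s + 1L else NA_integer_,
         x_c = (seq_len(nx) - 0.5) * dx,
         y_c = (seq_len(ny) - 0.5) * dy,
         x_f = (0:nx) * dx,
         y_f = (0:ny) * dy),
    class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf(
    "<flow_grid> %d x %d cells (dx = %g um, dy = %g um)%s\n",
    x$nx, x$ny, x$dx * 1e6, x$dy * 1e6,
    if (!is.na(x$j_mem)) sprintf(", membrane above row %d", x$ny_s) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# operator assembly

# 5-point Laplacian for interior u faces (i = 2..nx, j = 1..ny), vectorised
# column-major over an (nx-1) x ny layout. Tangential Dirichlet walls
# (bottom, top, membrane from both sides) enter through linear ghost cells
# (diagonal modification); side walls carry u = 0 exactly on the face.
build_Lu <- function(g) {
  per <- isTRUE(g$periodic)
  nxu <- if (per) g$nx else g$nx - 1L
  ny <- g$ny
  idx <- function(i, j) i + (j - 1L) * nxu
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b)
    vv <<- c(vv, rep_len(v, length(a)))
  }
  ax <- 1 / g$dx^2; ay <- 1 / g$dy^2
  I <- rep(seq_len(nxu), ny); J <- rep(seq_len(ny), each = nxu)
  ctr <- idx(I, J)
  # ghost rows: bottom (j=1), top (j=ny), membrane-adjacent rows
  ghost_low <- (J == 1L) | (!is.na(g$j_mem) & J == g$ny_s + 1L)
  ghost_high <- (J == ny) | (!is.na(g$j_mem) & J == g$ny_s)
  diagv <- -2 * ax - (2 + ghost_low + ghost_high) * ay
  add(ctr, ctr, diagv)
  if (per) {
    add(ctr, idx(ifelse(I == 1L, nxu, I - 1L), J), ax)
    add(ctr, idx(ifelse(I == nxu, 1L, I + 1L), J), ax)
  } else {
    w <- I > 1L;  add(ctr[w], idx(I[w] - 1L, J[w]), ax)
    w <- I < nxu; add(ctr[w], idx(I[w] + 1L, J[w]), ax)
  }
  w <- !ghost_low;  add(ctr[w], idx(I[w], J[w] - 1L), ay)
  w <- !ghost_high; add(ctr[w], idx(I[w], J[w] + 1L), ay)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nxu * ny, nxu * ny))
}

# Laplacian for interior v faces (i = 1..nx, j in jv_rows), with Dirichlet
# neighbours on prescribed rows (bottom, top, membrane) handled through the
# bc vector and ghost cells at the side walls.
build_Lv <- function(g, jv_rows) {
  nx <- g$nx; nj <- length(jv_rows)
  jpos <- integer(g$ny + 1L); jpos[jv_rows] <- seq_len(nj)
  idx <- function(i, jp) i + (jp - 1L) * nx
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b)
    vv <<- c(vv, rep_len(v, length(a)))
  }
  ax <- 1 / g$dx^2; ay <- 1 / g$dy^2
  I <- rep(seq_len(nx), nj); J <- rep(jv_rows, each = nx)
  JP <- rep(seq_len(nj), each = nx)
  ctr <- idx(I, JP)
  per <- isTRUE(g$periodic)
  if (per) {
    add(ctr, ctr, -2 * ax - 2 * ay)
    add(ctr, idx(ifelse(I == 1L, nx, I - 1L), JP), ax)
    add(ctr, idx(ifelse(I == nx, 1L, I + 1L), JP), ax)
  } else {
    side_l <- I == 1L; side_r <- I == nx
    add(ctr, ctr, -(2 + side_l + side_r) * ax - 2 * ay)
    w <- !side_l; add(ctr[w], idx(I[w] - 1L, JP[w]), ax)
    w <- !side_r; add(ctr[w], idx(I[w] + 1L, JP[w]), ax)
  }
  # vertical neighbours: link only when the neighbour row is itself unknown
  nb_dn <- J - 1L; w <- nb_dn >= 1L & jpos[pmax(nb_dn, 1L)] > 0L
  add(ctr[w], idx(I[w], jpos[nb_dn[w]]), ay)
  nb_up <- J + 1L; w <- nb_up <= g$ny + 1L & jpos[pmin(nb_up, g$ny + 1L)] > 0L
  add(ctr[w], idx(I[w], jpos[nb_up[w]]), ay)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * nj, nx * nj))
}

# Pressure/projection matrix including the Darcy membrane coupling.
# Returns the matrix with unknown 1 eliminated (p[1] pinned to 0).
build_Mp <- function(g, dt_over_rho, K) {
  nx <- g$nx; ny <- g$ny
  idx <- function(i, j) i + (j - 1L) * nx
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b)
    vv <<- c(vv, rep_len(v, length(a)))
  }
  ax <- dt_over_rho / g$dx^2
  ay <- dt_over_rho / g$dy^2
  I <- rep(seq_len(nx), ny); J <- rep(seq_len(ny), each = nx)
  ctr <- idx(I, J)
  # x links
  if (isTRUE(g$periodic)) {
    add(ctr, idx(ifelse(I == 1L, nx, I - 1L), J), -ax); add(ctr, ctr, ax)
    add(ctr, idx(ifelse(I == nx, 1L, I + 1L), J), -ax); add(ctr, ctr, ax)
  } else {
    w <- I > 1L;  add(ctr[w], idx(I[w] - 1L, J[w]), -ax); add(ctr[w], ctr[w], ax)
    w <- I < nx;  add(ctr[w], idx(I[w] + 1L, J[w]), -ax); add(ctr[w], ctr[w], ax)
  }
  # y links across interior (non-membrane) faces
  is_mem_below <- !is.na(g$j_mem) & J == g$j_mem       # face j_mem below cell row j = j_mem
  is_mem_above <- !is.na(g$j_mem) & J == g$j_mem - 1L
  w <- J > 1L & !is_mem_below
  add(ctr[w], idx(I[w], J[w] - 1L), -ay); add(ctr[w], ctr[w], ay)
  w <- J < ny & !is_mem_above
  add(ctr[w], idx(I[w], J[w] + 1L), -ay); add(ctr[w], ctr[w], ay)
  # membrane faces: flux K * (p_below - p_above) replaces dt/rho gradient
  if (!is.na(g$j_mem) && K > 0) {
    am <- K / g$dy
    w <- is_mem_below
    add(ctr[w], idx(I[w], J[w] - 1L), -am); add(ctr[w], ctr[w], am)
    w <- is_mem_above
    add(ctr[w], idx(I[w], J[w] + 1L), -am); add(ctr[w], ctr[w], am)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(nx * ny, nx * ny))
  # pin one pressure cell per connected component (two when the membrane is
  # impermeable and splits the domain)
  pins <- 1L
  if (!is.na(g$j_mem) && K == 0) pins <- c(pins, idx(1L, g$j_mem))
  list(M = M[-pins, -pins, drop = FALSE], pins = pins, n = nx * ny)
}

# ---------------------------------------------------------------------------
# flow problem and time stepping

#' Define a discrete flow problem
#'
#' Assembles and factorises the implicit operators for the two-layer (or
#' single-channel) incompressible Navier-Stokes problem: Crank-Nicolson
#' viscous terms, explicit (Adams-Bashforth) advection, and a pressure
#' projection that enforces the discrete continuity equation, with the
#' Darcy membrane condition built into the projection. Boundary conditions:
#' no-slip on rigid walls, prescribed normal velocity on the deforming top
#' wall (volume-compensated so the closed box stays compatible with
#' incompressibility), zero tangential slip at the membrane on both sides.
#'
#' @param grid A [flow_grid()] or [channel_grid()].
#' @param wall A `wall_motion_field` driving the top wall, or `NULL` for a
#'   rigid top wall.
#' @param props [fluid_properties()].
#' @param membrane [membrane_model()]; ignored for single-layer grids.
#' @param dt_s Time step in s. Defaults to `period/120` when `wall` is given
#'   (the stimulus period must be resolved by at least 100 steps).
#' @param fx_m_s2 Constant axial body force per unit mass (m/s^2), e.g. to
#'   drive a Poiseuille benchmark flow.
#' @param ub_fun Optional tangential velocity of the bottom wall,
#'   `function(x_m, t_s)` returning m/s (Stokes-plate benchmark).
#' @return A `flow_problem` object.
#' @export
flow_problem <- function(grid, wall = NULL, props = fluid_properties(),
                         membrane = membrane_model(), dt_s = NULL,
                         fx_m_s2 = 0, ub_fun = NULL) {
  stopifnot(inherits(grid, "flow_grid"))
  stopifnot(is.null(wall) || inherits(wall, "wall_motion_field"))
  stopifnot(inherits(props, "fluid_properties"))
  stopifnot(inherits(membrane, "membrane_model"))
  if (is.null(dt_s)) {
    if (is.null(wall)) stop("`dt_s` is required when `wall` is NULL", call. = FALSE)
    dt_s <- wall$period_s / 120
  }
  stop_if_not_scalar_pos(dt_s, "dt_s")
  if (!is.null(wall) && wall$period_s / dt_s < 100 - 1e-9) {
    stop("`dt_s` must resolve the stimulus period by at least 100 steps",
         call. = FALSE)
  }
  g <- grid
  jv_rows <- setdiff(2:g$ny, g$j_mem)  # unknown v rows
  Lu <- build_Lu(g)
  Lv <- build_Lv(g, jv_rows)
  cu <- 0.5 * props$nu * dt_s
  n_u <- nrow(Lu); n_v <- nrow(Lv)
  Au <- Matrix::Diagonal(n_u) - cu * Lu
  Av <- Matrix::Diagonal(n_v) - cu * Lv
  K <- if (is.na(g$j_mem)) 0 else membrane$K
  Mp <- build_Mp(g, dt_s / props$rho, K)
  structure(
    list(grid = g, wall = wall, props = props, membrane = membrane,
         dt = dt_s, fx = fx_m_s2, ub_fun = ub_fun,
         jv_rows = jv_rows, Lu = Lu, Lv = Lv, p_pins = Mp$pins,
         chol_u = Matrix::Cholesky(methods::as(Au, "symmetricMatrix")),
         chol_v = Matrix::Cholesky(methods::as(Av, "symmetricMatrix")),
         chol_p = Matrix::Cholesky(methods::as(Mp$M, "symmetricMatrix"))),
    class = "flow_problem")
}

# rest state
flow_state_init <- function(g) {
  list(u = matrix(0, g$nx + 1L, g$ny),
       v = matrix(0, g$nx, g$ny + 1L),
       p = matrix(0, g$nx, g$ny),
       t = 0, div_norm = 0)
}

# prescribed top-wall normal velocity at time t (volume-compensated), at the
# x-locations of the v faces; `ramp` in [0,1] soft-starts the forcing
wall_w <- function(prob, t, ramp = 1) {
  g <- prob$grid
  if (is.null(prob$wall)) return(numeric(g$nx))
  w <- ramp * wall_velocity_si(prob$wall, g$x_c, t)
  w - mean(w)
}

wall_ub <- function(prob, t) {
  g <- prob$grid
  if (is.null(prob$ub_fun)) return(numeric(g$nx + 1L))
  prob$ub_fun(g$x_f, t)
}

# central-difference advection terms at interior u and v faces
advect_terms <- function(prob, st, ub) {
  g <- prob$grid; nx <- g$nx; ny <- g$ny
  per <- isTRUE(g$periodic)
  u <- st$u; v <- st$v
  dx <- g$dx; dy <- g$dy
  iu <- if (per) 1:nx else 2:nx  # unknown u faces
  # --- u momentum
  ui <- u[iu, , drop = FALSE]
  if (per) {
    dudx <- (u[2:(nx + 1), , drop = FALSE] -
             u[c(nx, 1:(nx - 1)), , drop = FALSE]) / (2 * dx)
  } else {
    dudx <- (u[3:(nx + 1), , drop = FALSE] - u[1:(nx - 1), , drop = FALSE]) / (2 * dx)
  }
  # vertical ghosts (tangential Dirichlet walls)
  ughost_b <- 2 * ub[iu] - u[iu, 1]
  ughost_t <- -u[iu, ny]
  uup <- cbind(u[iu, 2:ny, drop = FALSE], ughost_t)
  udn <- cbind(ughost_b, u[iu, 1:(ny - 1), drop = FALSE])
  if (!is.na(g$j_mem)) {
    js <- g$ny_s
    uup[, js] <- -u[iu, js]            # ghost above row js across membrane
    udn[, js + 1L] <- -u[iu, js + 1L]  # ghost below row js+1
  }
  dudy <- (uup - udn) / (2 * dy)
  ivW <- if (per) c(nx, 1:(nx - 1)) else 1:(nx - 1)  # v column west of each u face
  ivE <- if (per) 1:nx else 2:nx
  v_at_u <- 0.25 * (v[ivW, 1:ny, drop = FALSE] + v[ivE, 1:ny, drop = FALSE] +
                    v[ivW, 2:(ny + 1), drop = FALSE] + v[ivE, 2:(ny + 1), drop = FALSE])
  Nu <- ui * dudx + v_at_u * dudy
  # --- v momentum, unknown faces i=1..nx, j in jv_rows
  jv <- prob$jv_rows
  vi <- v[, jv, drop = FALSE]
  dvdy <- (v[, jv + 1L, drop = FALSE] - v[, jv - 1L, drop = FALSE]) / (2 * dy)
  if (per) {
    vl <- v[c(nx, 1:(nx - 1)), jv, drop = FALSE]
    vr <- v[c(2:nx, 1L), jv, drop = FALSE]
  } else {
    vl <- rbind(-v[1, jv], v[1:(nx - 1), jv, drop = FALSE])
    vr <- rbind(v[2:nx, jv, drop = FALSE], -v[nx, jv])
  }
  dvdx <- (vr - vl) / (2 * dx)
  u_at_v <- 0.25 * (u[1:nx, jv - 1L, drop = FALSE] + u[1:nx, jv, drop = FALSE] +
                    u[2:(nx + 1), jv - 1L, drop = FALSE] + u[2:(nx + 1), jv, drop = FALSE])
  Nv <- u_at_v * dvdx + vi * dvdy
  list(Nu = as.vector(Nu), Nv = as.vector(Nv))
}

# boundary-condition contribution of the u Laplacian (ghost walls) at time t
bc_u_vec <- function(prob, ub) {
  g <- prob$grid
  if (isTRUE(g$periodic)) {
    m <- matrix(0, g$nx, g$ny)
    m[, 1] <- 2 * ub[1:g$nx] / g$dy^2
  } else {
    m <- matrix(0, g$nx - 1L, g$ny)
    m[, 1] <- 2 * ub[2:g$nx] / g$dy^2
  }
  as.vector(m)
}

# boundary contribution of the v Laplacian: prescribed neighbour rows
bc_v_vec <- function(prob, w_top, v_mem) {
  g <- prob$grid; jv <- prob$jv_rows
  m <- matrix(0, g$nx, length(jv))
  jpos <- match(g$ny, jv)
  if (!is.na(jpos)) m[, jpos] <- m[, jpos] + w_top / g$dy^2
  if (!is.na(g$j_mem)) {
    jpos <- match(g$j_mem - 1L, jv)
    if (!is.na(jpos)) m[, jpos] <- m[, jpos] + v_mem / g$dy^2
    jpos <- match(g$j_mem + 1L, jv)
    if (!is.na(jpos)) m[, jpos] <- m[, jpos] + v_mem / g$dy^2
  }
  as.vector(m)
}

#' Advance a flow state
#'
#' Integrates the discrete Navier-Stokes equations by `n_steps` time steps
#' with the advective term retained, enforcing discrete continuity after
#' every step through the pressure projection.
#'
#' @param problem A [flow_problem()].
#' @param state A flow state as returned by a previous call, or `NULL` to
#'   start from rest.
#' @param n_steps Number of steps to take.
#' @param ramp_fun Optional `function(t_s)` in `[0, 1]` scaling the wall
#'   forcing (soft start); default constant 1.
#' @param div_tol Maximum allowed discrete divergence norm (relative to
#'   max|u|/dx); exceeding it raises a solver-failure error.
#' @return The advanced state (list with `u`, `v`, `p`, `t`, `div_norm`).
#' @export
advance_flow <- function(problem, state = NULL, n_steps = 1, ramp_fun = NULL,
                         div_tol = 1e-8) {
  stopifnot(inherits(problem, "flow_problem"))
  g <- problem$grid; dt <- problem$dt
  nx <- g$nx; ny <- g$ny
  st <- if (is.null(state)) flow_state_init(g) else state
  cu <- 0.5 * problem$props$nu * dt
  dtor <- dt / problem$props$rho
  jv <- problem$jv_rows
  K <- if (is.na(g$j_mem)) 0 else problem$membrane$K
  Nprev <- st$Nprev
  for (k in seq_len(n_steps)) {
    t0 <- st$t; t1 <- st$t + dt
    r0 <- if (is.null(ramp_fun)) 1 else ramp_fun(t0)
    r1 <- if (is.null(ramp_fun)) 1 else ramp_fun(t1)
    ub0 <- wall_ub(problem, t0); ub1 <- wall_ub(problem, t1)
    w1 <- wall_w(problem, t1, r1)
    v_mem0 <- if (!is.na(g$j_mem)) st$v[, g$j_mem] else NULL
    adv <- advect_terms(problem, st, ub0)
    if (is.null(Nprev)) Nprev <- adv
    iu <- if (isTRUE(g$periodic)) 1:nx else 2:nx
    u_in <- as.vector(st$u[iu, , drop = FALSE])
    v_in <- as.vector(st$v[, jv, drop = FALSE])
    rhs_u <- u_in +
      dt * (-(1.5 * adv$Nu - 0.5 * Nprev$Nu) + problem$fx) +
      cu * (as.vector(problem$Lu %*% u_in) + bc_u_vec(problem, ub0)) +
      cu * bc_u_vec(problem, ub1)
    bcv0 <- bc_v_vec(problem, wall_w(problem, t0, r0), v_mem0)
    bcv1 <- bc_v_vec(problem, w1, v_mem0)  # membrane value lagged one step
    rhs_v <- v_in +
      dt * (-(1.5 * adv$Nv - 0.5 * Nprev$Nv)) +
      cu * (as.vector(problem$Lv %*% v_in) + bcv0) +
      cu * bcv1
    u_star <- st$u; v_star <- st$v
    u_star[iu, ] <- matrix(as.numeric(Matrix::solve(problem$chol_u, rhs_u, system = "A")),
                           length(iu), ny)
    if (isTRUE(g$periodic)) u_star[nx + 1L, ] <- u_star[1L, ]
    v_star[, jv] <- matrix(as.numeric(Matrix::solve(problem$chol_v, rhs_v, system = "A")),
                           nx, length(jv))
    v_star[, ny + 1L] <- w1
    v_star[, 1L] <- 0
    if (!is.na(g$j_mem)) v_star[, g$j_mem] <- 0  # Darcy predictor (u_bm = 0)
    # projection
    divv <- (u_star[2:(nx + 1), , drop = FALSE] - u_star[1:nx, , drop = FALSE]) / g$dx +
            (v_star[, 2:(ny + 1), drop = FALSE] - v_star[, 1:ny, drop = FALSE]) / g$dy
    b <- -as.vector(divv)
    sol <- as.numeric(Matrix::solve(problem$chol_p, b[-problem$p_pins], system = "A"))
    pv <- numeric(nx * ny)
    pv[-problem$p_pins] <- sol
    p <- matrix(pv, nx, ny)
    u_new <- u_star
    if (isTRUE(g$periodic)) {
      u_new[1:nx, ] <- u_star[1:nx, , drop = FALSE] -
        dtor * (p - p[c(nx, 1:(nx - 1)), , drop = FALSE]) / g$dx
      u_new[nx + 1L, ] <- u_new[1L, ]
    } else {
      u_new[2:nx, ] <- u_star[2:nx, , drop = FALSE] -
        dtor * (p[2:nx, , drop = FALSE] - p[1:(nx - 1), , drop = FALSE]) / g$dx
    }
    v_new <- v_star
    v_new[, jv] <- v_star[, jv, drop = FALSE] -
      dtor * (p[, jv, drop = FALSE] - p[, jv - 1L, drop = FALSE]) / g$dy
    if (!is.na(g$j_mem) && K > 0) {
      v_new[, g$j_mem] <- -K * (p[, g$j_mem] - p[, g$j_mem - 1L])
    }
    divn <- (u_new[2:(nx + 1), , drop = FALSE] - u_new[1:nx, , drop = FALSE]) / g$dx +
            (v_new[, 2:(ny + 1), drop = FALSE] - v_new[, 1:ny, drop = FALSE]) / g$dy
    u_scale <- max(max(abs(u_new)), max(abs(v_new)), 1e-300)
    div_norm <- sqrt(mean(divn^2))
    if (!is.finite(div_norm)) {
      stop("flow solver diverged (non-finite fields) at t = ", t1, call. = FALSE)
    }
    if (div_norm > div_tol * u_scale / g$dx) {
      stop(sprintf(
        "continuity residual %0.3g exceeds tolerance (%0.3g) at t = %g s",
        div_norm, div_tol * u_scale / g$dx, t1), call. = FALSE)
    }
    st <- list(u = u_new, v = v_new, p = p, t = t1,
               div_norm = div_norm, Nprev = adv)
    Nprev <- adv
  }
  st
}

#' Solver configuration for periodic runs
#'
#' @param n_cycles_max Maximum number of stimulus cycles to integrate.
#' @param tol_periodic Relative L2 change between consecutive cycle-averaged
#'   velocity fields below which the flow is declared periodically steady.
#' @param ramp_cycles Number of initial cycles over which the wall forcing is
#'   ramped up smoothly (reduces the startup transient that would otherwise
#'   contaminate the period average).
#' @param min_cycles Minimum cycles before convergence may be declared
#'   (at least `ramp_cycles + 2`).
#' @return A `solver_config` object.
#' @export
solver_config <- function(n_cycles_max = 25, tol_periodic = 1e-3,
                          ramp_cycles = 3, min_cycles = ramp_cycles + 2) {
  structure(list(n_cycles_max = n_cycles_max, tol_periodic = tol_periodic,
                 ramp_cycles = ramp_cycles,
                 min_cycles = max(min_cycles, ramp_cycles + 2)),
            class = "solver_config")
}

#' Run a wall-driven flow to its periodic steady state
#'
#' Integrates cycle by cycle until the relative L2 difference between
#' consecutive cycle-averaged velocity fields drops below
#' `config$tol_periodic`, then reports the converged cycle average as the
#' drift (steady-streaming) field. Non-convergence within
#' `config$n_cycles_max` is flagged, not silent.
#'
#' @param problem A [flow_problem()] with a non-`NULL` wall.
#' @param config A [solver_config()].
#' @return A `flow_solution` with face-centred drift fields `u_drift`
#'   (m/s, `(nx+1) x ny`) and `v_drift` (`nx x (ny+1)`), oscillatory RMS
#'   amplitude, convergence diagnostics and the final state.
#' @export
run_periodic <- function(problem, config = solver_config()) {
  stopifnot(inherits(problem, "flow_problem"))
  if (is.null(problem$wall)) {
    stop("`run_periodic()` needs a wall-driven problem", call. = FALSE)
  }
  g <- problem$grid
  period <- problem$wall$period_s
  nsteps <- round(period / problem$dt)
  if (abs(nsteps * problem$dt - period) > 1e-9 * period) {
    stop("`dt_s` must divide the stimulus period", call. = FALSE)
  }
  t_ramp <- config$ramp_cycles * period
  ramp_fun <- function(t) ifelse(t >= t_ramp, 1, 0.5 * (1 - cos(pi * t / t_ramp)))
  st <- NULL
  avg_prev <- NULL
  metric <- NA_real_
  metrics <- numeric(0)
  converged <- FALSE
  osc_ms <- 0
  div_max <- 0
  n_cyc <- 0L
  for (cyc in seq_len(config$n_cycles_max)) {
    acc_u <- matrix(0, g$nx + 1L, g$ny)
    acc_v <- matrix(0, g$nx, g$ny + 1L)
    osc_ms <- 0
    prev_u <- if (is.null(st)) flow_state_init(g)$u else st$u
    prev_v <- if (is.null(st)) flow_state_init(g)$v else st$v
    for (s in seq_len(nsteps)) {
      st <- advance_flow(problem, st, 1, ramp_fun = ramp_fun)
      acc_u <- acc_u + 0.5 * (prev_u + st$u)
      acc_v <- acc_v + 0.5 * (prev_v + st$v)
      osc_ms <- osc_ms + mean(st$u^2) + mean(st$v^2)
      div_max <- max(div_max, st$div_norm)
      prev_u <- st$u; prev_v <- st$v
    }
    n_cyc <- cyc
    avg <- list(u = acc_u / nsteps, v = acc_v / nsteps)
    if (!is.null(avg_prev) && cyc > config$ramp_cycles) {
      num <- sqrt(mean((avg$u - avg_prev$u)^2) + mean((avg$v - avg_prev$v)^2))
      den <- sqrt(mean(avg$u^2) + mean(avg$v^2))
      metric <- if (den == 0) 0 else num / den
      metrics <- c(metrics, metric)
      if (cyc >= config$min_cycles && metric < config$tol_periodic) {
        converged <- TRUE
      }
    }
    avg_prev <- avg
    if (converged) break
  }
  if (!converged && !is.na(metric) && metric == 0) converged <- TRUE
  structure(
    list(grid = g, wall = problem$wall, problem = problem,
         u_drift = avg_prev$u, v_drift = avg_prev$v,
         osc_rms = sqrt(osc_ms / nsteps),
         period_s = period, n_cycles = n_cyc, converged = converged,
         periodicity = metric, periodicity_history = metrics,
         div_norm_max = div_max, state = st),
    class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "<flow_solution> %s after %d cycles (periodicity %0.3g); max |u_D| = %0.3g um/s\n",
    if (x$converged) "converged" else "NOT converged", x$n_cycles,
    x$periodicity, 1e6 * max(abs(x$u_drift))))
  invisible(x)
}

#' Period-averaged drift velocity
#'
#' For a converged [run_periodic()] solution, returns the drift field; for a
#' raw cycle history (list of velocity snapshot matrices spanning exactly one
#' period at uniform sampling), computes the trapezoidal period average.
#'
#' @param x A `flow_solution`, or a list of numeric arrays sampled uniformly
#'   over one period (first and last sample one period apart).
#' @param period_s Period in seconds (required for a raw history).
#' @return For a solution, a tibble of cell-centred drift velocities
#'   (`x_mm`, `y_um`, `layer`, `u_um_s`, `v_um_s`); for a raw history, the
#'   averaged array.
#' @export
drift_velocity <- function(x, period_s = NULL) {
  if (inherits(x, "flow_solution")) {
    return(tidy.flow_solution(x))
  }
  if (!is.list(x) || length(x) < 3) {
    stop("history must span one full period with at least 3 samples", call. = FALSE)
  }
  if (is.null(period_s)) stop("`period_s` is required for a raw history", call. = FALSE)
  n <- length(x)
  # trapezoid over [t, t+T]: endpoints get half weight
  acc <- x[[1]] * 0.5
  for (k in 2:(n - 1)) acc <- acc + x[[k]]
  acc <- acc + x[[n]] * 0.5
  acc / (n - 1)
}

#' Tidy a flow solution into a cell-centred drift table
#'
#' @param x A `flow_solution`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `y_um`, `layer` ("scala" or "corti"),
#'   `u_um_s`, `v_um_s` (drift velocity components in micrometres/s).
#' @export
tidy.flow_solution <- function(x, ...) {
  g <- x$grid
  uc <- 0.5 * (x$u_drift[1:g$nx, , drop = FALSE] + x$u_drift[2:(g$nx + 1), , drop = FALSE])
  vc <- 0.5 * (x$v_drift[, 1:g$ny, drop = FALSE] + x$v_drift[, 2:(g$ny + 1), drop = FALSE])
  layer <- if (is.na(g$j_mem)) rep("channel", g$ny) else
    rep(c("scala", "corti"), c(g$ny_s, g$ny_c))
  tibble(
    x_mm = rep(g$x_c * 1000, g$ny),
    y_um = rep(g$y_c * 1e6, each = g$nx),
    layer = rep(layer, each = g$nx),
    u_um_s = as.vector(uc) * 1e6,
    v_um_s = as.vector(vc) * 1e6)
}

#' @export
glance.flow_solution <- function(x, ...) {
  td <- tidy(x)
  tibble(converged = x$converged, n_cycles = x$n_cycles,
         periodicity = x$periodicity, div_norm_max = x$div_norm_max,
         max_drift_um_s = max(sqrt(td$u_um_s^2 + td$v_um_s^2)),
         osc_rms_m_s = x$osc_rms)
}

#' Summarise drift by layer over an axial window
#'
#' Reports the mean axial drift at Corti-fluid mid-height and over the lower
#' half of the scala-tympani layer (the return stream occupies the scala
#' interior; within one oscillatory boundary-layer thickness of the rigid
#' floor the drift decays to zero, so the single bottom row is not
#' representative), the net axial drift volume flux of each layer, and the
#' maximum (over x) of the absolute net cross-sectional flux through both
#' layers combined, which should vanish in a closed box (return-flow
#' compensation).
#'
#' @param sol A `flow_solution` on a two-layer grid.
#' @param x_range_mm Axial window (mm) over which to average, e.g. the tail
#'   region of the traveling wave.
#' @return One-row tibble with columns `u_corti_um_s`, `u_scala_lower_um_s`,
#'   `flux_corti_m2_s`, `flux_scala_m2_s`, `net_flux_ratio`.
#' @export
drift_summary <- function(sol, x_range_mm) {
  stopifnot(inherits(sol, "flow_solution"))
  g <- sol$grid
  if (is.na(g$j_mem)) stop("`drift_summary()` needs a two-layer grid", call. = FALSE)
  xf_mm <- g$x_f * 1000
  sel <- which(xf_mm >= x_range_mm[1] & xf_mm <= x_range_mm[2])
  sel <- sel[sel >= 2 & sel <= g$nx]  # interior faces only
  u <- sol$u_drift
  rows_c <- (g$ny_s + 1L):g$ny
  rows_s <- 1:g$ny_s
  rows_s_low <- 1:max(1L, g$ny_s %/% 2L)
  j_mid_c <- g$ny_s + max(1L, ceiling(g$ny_c / 2))
  flux_c <- colSums(t(u[sel, rows_c, drop = FALSE])) * g$dy  # per x-face, m^2/s
  flux_s <- colSums(t(u[sel, rows_s, drop = FALSE])) * g$dy
  net <- abs(flux_c + flux_s)
  single_max <- max(abs(c(flux_c, flux_s)))
  tibble(
    u_corti_um_s = mean(u[sel, j_mid_c]) * 1e6,
    u_scala_lower_um_s = mean(u[sel, rows_s_low]) * 1e6,
    flux_corti_m2_s = mean(flux_c),
    flux_scala_m2_s = mean(flux_s),
    net_flux_ratio = if (single_max > 0) max(net) / single_max else 0)
}
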