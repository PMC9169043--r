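# Transient incompressible Newtonian flow on the labelled staggered grid.
#
# Discretization: MAC staggered finite volumes; central second-order
# diffusion; flux-limited (van Leer) second-order upwind advection;
# second-order strong-stability-preserving Runge-Kutta (Heun) in time with a
# pressure projection per stage via a prefactorized sparse Poisson solve
# (SSP time stepping is the standard stable pairing with limited advection).
# The outlet 0D models couple through the projection: within
# a step the projected outlet flux is affine in the outlet pressures and the
# backward-Euler 0D models are affine Q(P), so the coupled outlet pressures
# are obtained from a small linear solve and the sub-iteration loop only
# verifies the residual.
#
# Units: SI internally (m, s, Pa, m^3/s per metre of out-of-plane depth);
# grid spacing converts from mm at context build time.

#' Blood material properties
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity Pa s.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1055, dynamic_viscosity = 3.5e-3) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Flow-solver configuration
#'
#' Defaults follow common practice for pulsatile vascular runs: a fixed
#' 10 ms step (100 steps per 1 s cardiac cycle), at most 50 sub-iterations
#' per step at an RMS residual tolerance of 1e-5, and up to 10 warm-up
#' cycles to reach a periodic flow field.
#'
#' @param dt time step (s); must divide the cardiac period evenly.
#' @param max_subiterations cap on pressure-coupling sub-iterations.
#' @param rms_residual_tol RMS residual declaring a step converged.
#' @param n_warmup_cycles cap on cycles run to reach periodicity.
#' @param snapshots_per_cycle snapshots retained per cycle; must divide the
#'   number of steps per cycle.
#' @param periodic_tol cycle-to-cycle RMS velocity change (relative)
#'   declaring the flow periodic.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = 0.01, max_subiterations = 50,
                          rms_residual_tol = 1e-5, n_warmup_cycles = 10,
                          snapshots_per_cycle = 100, periodic_tol = 5e-3) {
  stopifnot(dt > 0, max_subiterations >= 1, rms_residual_tol > 0,
            n_warmup_cycles >= 1, snapshots_per_cycle >= 1, periodic_tol > 0)
  structure(
    list(dt = dt, max_subiterations = max_subiterations,
         rms_residual_tol = rms_residual_tol,
         n_warmup_cycles = n_warmup_cycles,
         snapshots_per_cycle = snapshots_per_cycle,
         periodic_tol = periodic_tol),
    class = "solver_config"
  )
}

# van Leer limited slope (harmonic mean of one-sided differences)
.vanleer <- function(a, b) {
  s <- a * b
  out <- numeric(length(a))
  pos <- s > 0
  out[pos] <- 2 * s[pos] / (a[pos] + b[pos])
  dim(out) <- dim(a)
  out
}

# MUSCL face values along dim 1: phi is n x m, w (advecting velocity at the
# n-1 interior interfaces) is (n-1) x m; returns (n-1) x m face values.
.muscl_dim1 <- function(phi, w) {
  n <- nrow(phi)
  d <- phi[-1, , drop = FALSE] - phi[-n, , drop = FALSE]     # (n-1) x m
  zero <- matrix(0, 1, ncol(phi))
  dm <- rbind(zero, d)      # d[k-1] aligned to cell k
  dp <- rbind(d, zero)      # d[k]   aligned to cell k
  slope <- .vanleer(dm, dp) # n x m limited slope per cell
  up <- phi[-n, , drop = FALSE] + 0.5 * slope[-n, , drop = FALSE]
  dn <- phi[-1, , drop = FALSE] - 0.5 * slope[-1, , drop = FALSE]
  ifelse(w >= 0, up, dn)
}

.muscl_dim2 <- function(phi, w) {
  t(.muscl_dim1(t(phi), t(w)))
}

# --- solver context: everything derivable from (grid, props, cfg) ----------

.build_solver_ctx <- function(grid, props, cfg) {
  nx <- grid$nx; ny <- grid$ny
  hm <- grid$h * 1e-3
  fluid <- grid$fluid
  ut <- grid$u_type; vt <- grid$v_type

  id <- matrix(NA_integer_, nx, ny)
  id[fluid] <- seq_len(sum(fluid))
  N <- sum(fluid)

  # Poisson assembly (negative Laplacian, scaled by hm^2): M p = b
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagc <- numeric(N)
  # outlet bookkeeping: per cell, Dirichlet contributions per outlet label
  out_labels <- intersect(
    OUTLET_FACE_CODES,
    c(unique(as.vector(ut)), unique(as.vector(vt)))
  )
  dir_cells <- lapply(out_labels, function(l) integer(0))
  names(dir_cells) <- as.character(out_labels)

  cells <- which(fluid, arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    c0 <- id[i, j]
    faces <- list(
      list(type = ut[i, j],     nb = if (i > 1) id[i - 1, j] else NA),
      list(type = ut[i + 1, j], nb = if (i < nx) id[i + 1, j] else NA),
      list(type = vt[i, j],     nb = if (j > 1) id[i, j - 1] else NA),
      list(type = vt[i, j + 1], nb = if (j < ny) id[i, j + 1] else NA)
    )
    for (f in faces) {
      if (f$type == FACE_INTERIOR) {
        diagc[c0] <- diagc[c0] + 1
        ii <- c(ii, c0); jj <- c(jj, f$nb); xx <- c(xx, -1)
      } else if (f$type %in% OUTLET_FACE_CODES) {
        diagc[c0] <- diagc[c0] + 2
        lab <- as.character(f$type)
        dir_cells[[lab]] <- c(dir_cells[[lab]], c0)
      }
      # WALL / INLET: homogeneous Neumann, no contribution
    }
  }
  M <- Matrix::sparseMatrix(
    i = c(seq_len(N), ii), j = c(seq_len(N), jj), x = c(diagc, xx),
    dims = c(N, N)
  )
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE, perm = TRUE)

  # inlet faces (left edge)
  inlet_rows <- which(ut[1, ] == FACE_INLET)
  yc_in <- (inlet_rows - 0.5) * hm
  y0 <- (min(inlet_rows) - 1) * hm
  y1 <- max(inlet_rows) * hm
  xi <- (yc_in - (y0 + y1) / 2) / ((y1 - y0) / 2)
  shape <- 1 - xi^2
  shape <- shape / (sum(shape) * hm)   # discrete flux of `shape` is exactly 1

  # outlet face index sets (arr indices + outward sign)
  outlet_faces <- lapply(out_labels, function(l) {
    uf <- which(ut == l, arr.ind = TRUE)
    vf <- which(vt == l, arr.ind = TRUE)
    # adjacent fluid cell and outward sign per face
    u_sign <- if (nrow(uf)) ifelse(uf[, 1] > nx, 1, ifelse(uf[, 1] == 1, -1, NA)) else numeric(0)
    v_sign <- if (nrow(vf)) ifelse(vf[, 2] > ny, 1, ifelse(vf[, 2] == 1, -1, NA)) else numeric(0)
    if (any(is.na(c(u_sign, v_sign)))) {
      stop("outlet faces must lie on the domain boundary")
    }
    u_cell <- if (nrow(uf)) id[cbind(pmin(uf[, 1], nx), uf[, 2])] else integer(0)
    v_cell <- if (nrow(vf)) id[cbind(vf[, 1], pmin(vf[, 2], ny))] else integer(0)
    list(label = l, uf = uf, vf = vf, u_sign = u_sign, v_sign = v_sign,
         u_cell = u_cell, v_cell = v_cell)
  })
  names(outlet_faces) <- .face_label_name(out_labels)

  # masks for momentum evolution and tangential solid neighbours
  u_evolve <- ut == FACE_INTERIOR
  v_evolve <- vt == FACE_INTERIOR
  # u faces whose north/south neighbour u-face separates two solid cells
  u_solidN <- matrix(FALSE, nx + 1, ny)
  u_solidN[, -ny] <- ut[, -1, drop = FALSE] == FACE_INACTIVE
  u_solidS <- matrix(FALSE, nx + 1, ny)
  u_solidS[, -1] <- ut[, -ny, drop = FALSE] == FACE_INACTIVE
  v_solidE <- matrix(FALSE, nx, ny + 1)
  v_solidE[-nx, ] <- vt[-1, , drop = FALSE] == FACE_INACTIVE
  v_solidW <- matrix(FALSE, nx, ny + 1)
  v_solidW[-1, ] <- vt[-nx, , drop = FALSE] == FACE_INACTIVE
  # bottom-edge u ghosts: reflect at walls, copy over fistula-outlet columns
  u_bottom_copy <- rep(FALSE, nx + 1)
  fo_cols <- which(vt[, 1] == FACE_FISTULA_OUTLET)
  if (length(fo_cols)) {
    u_bottom_copy[fo_cols] <- TRUE
    u_bottom_copy[fo_cols + 1L] <- TRUE
  }

  list(
    nx = nx, ny = ny, hm = hm, fluid = fluid, id = id, N = N,
    rho = props$density, mu = props$dynamic_viscosity,
    nu = props$dynamic_viscosity / props$density,
    M = M, chol = chol, dir_cells = dir_cells, out_labels = out_labels,
    outlet_faces = outlet_faces,
    inlet_rows = inlet_rows, inlet_shape = shape,
    u_evolve = u_evolve, v_evolve = v_evolve,
    u_solidN = u_solidN, u_solidS = u_solidS,
    v_solidE = v_solidE, v_solidW = v_solidW,
    u_bottom_copy = u_bottom_copy,
    grid = grid, cfg = cfg
  )
}

.face_label_name <- function(codes) {
  nm <- c("wall", "inlet", "aortic_outlet", "coronary_outlet", "fistula_outlet")
  nm[match(codes, c(FACE_WALL, FACE_INLET, FACE_AORTIC_OUTLET,
                    FACE_CORONARY_OUTLET, FACE_FISTULA_OUTLET))]
}

# explicit momentum right-hand side F = -adv + nu * lap, full lattices
.momentum_rhs <- function(ctx, u, v) {
  nx <- ctx$nx; ny <- ctx$ny; hm <- ctx$hm; nu <- ctx$nu

  ## --- u component -------------------------------------------------------
  uc <- 0.5 * (u[-(nx + 1), , drop = FALSE] + u[-1, , drop = FALSE])  # nx x ny
  Fx <- uc * .muscl_dim1(u, uc)
  dFx <- matrix(0, nx + 1, ny)
  dFx[2:nx, ] <- (Fx[-1, , drop = FALSE] - Fx[-nx, , drop = FALSE]) / hm
  # corner advecting velocity vc on the (nx+1) x (ny+1) u-lattice y-interfaces
  v_xpad <- rbind(v[1, ], v, v[nx, ])                     # (nx+2) x (ny+1)
  vc <- 0.5 * (v_xpad[-(nx + 2), , drop = FALSE] + v_xpad[-1, , drop = FALSE])
  Gy <- matrix(0, nx + 1, ny + 1)
  if (ny > 1) {
    Gy[, 2:ny] <- vc[, 2:ny, drop = FALSE] *
      .muscl_dim2(u, vc[, 2:ny, drop = FALSE])
  }
  Gy[, 1] <- vc[, 1] * u[, 1]
  Gy[, ny + 1] <- vc[, ny + 1] * u[, ny]
  dGy <- (Gy[, -1, drop = FALSE] - Gy[, -(ny + 1), drop = FALSE]) / hm

  uE <- rbind(u[-1, , drop = FALSE], u[nx + 1, ])
  uW <- rbind(u[1, ], u[-(nx + 1), , drop = FALSE])
  ghost_top <- -u[, ny]
  ghost_bot <- ifelse(ctx$u_bottom_copy, u[, 1], -u[, 1])
  uN <- cbind(u[, -1, drop = FALSE], ghost_top)
  uS <- cbind(ghost_bot, u[, -ny, drop = FALSE])
  uN[ctx$u_solidN] <- -u[ctx$u_solidN]
  uS[ctx$u_solidS] <- -u[ctx$u_solidS]
  lap_u <- (uE - 2 * u + uW + uN - 2 * u + uS) / hm^2

  Fu <- -(dFx + dGy) + nu * lap_u
  Fu[!ctx$u_evolve] <- 0

  ## --- v component -------------------------------------------------------
  vcy <- 0.5 * (v[, -(ny + 1), drop = FALSE] + v[, -1, drop = FALSE])  # nx x ny
  Fy <- vcy * .muscl_dim2(v, vcy)
  dFy <- matrix(0, nx, ny + 1)
  dFy[, 2:ny] <- (Fy[, -1, drop = FALSE] - Fy[, -ny, drop = FALSE]) / hm
  u_ypad <- cbind(u[, 1], u, u[, ny])                      # (nx+1) x (ny+2)
  ucr <- 0.5 * (u_ypad[, -(ny + 2), drop = FALSE] + u_ypad[, -1, drop = FALSE])
  Gx <- matrix(0, nx + 1, ny + 1)
  if (nx > 1) {
    Gx[2:nx, ] <- ucr[2:nx, , drop = FALSE] *
      .muscl_dim1(v, ucr[2:nx, , drop = FALSE])
  }
  Gx[1, ] <- ucr[1, ] * v[1, ]
  Gx[nx + 1, ] <- ucr[nx + 1, ] * v[nx, ]
  dGx <- (Gx[-1, , drop = FALSE] - Gx[-(nx + 1), , drop = FALSE]) / hm

  vN <- cbind(v[, -1, drop = FALSE], v[, ny + 1])
  vS <- cbind(v[, 1], v[, -(ny + 1), drop = FALSE])
  vE <- rbind(v[-1, , drop = FALSE], v[nx, ])
  vW <- rbind(-v[1, ], v[-nx, , drop = FALSE])   # inlet plane: no-slip
  vE[ctx$v_solidE] <- -v[ctx$v_solidE]
  vW[ctx$v_solidW] <- -v[ctx$v_solidW]
  lap_v <- (vE - 2 * v + vW + vN - 2 * v + vS) / hm^2

  Fv <- -(dFy + dGx) + nu * lap_v
  Fv[!ctx$v_evolve] <- 0

  list(Fu = Fu, Fv = Fv)
}

.divergence <- function(ctx, u, v) {
  nx <- ctx$nx; ny <- ctx$ny
  d <- (u[-1, , drop = FALSE] - u[-(nx + 1), , drop = FALSE] +
          v[, -1, drop = FALSE] - v[, -(ny + 1), drop = FALSE]) / ctx$hm
  d[!ctx$fluid] <- 0
  d
}

# corrected velocities for pressure field p (vector over fluid cells) and
# outlet pressures Pout (named by outlet label)
.apply_projection <- function(ctx, ustar, vstar, pvec, Pout, kappa) {
  nx <- ctx$nx; ny <- ctx$ny; hm <- ctx$hm
  p <- matrix(0, nx, ny)
  p[ctx$fluid] <- pvec
  u <- ustar; v <- vstar
  gpx <- (p[-1, , drop = FALSE] - p[-nx, , drop = FALSE]) / hm  # (nx-1) x ny
  iu <- ctx$u_evolve
  u[2:nx, ][iu[2:nx, ]] <- ustar[2:nx, ][iu[2:nx, ]] -
    kappa * gpx[iu[2:nx, , drop = FALSE]]
  gpy <- (p[, -1, drop = FALSE] - p[, -ny, drop = FALSE]) / hm
  iv <- ctx$v_evolve
  v[, 2:ny][iv[, 2:ny]] <- vstar[, 2:ny][iv[, 2:ny]] -
    kappa * gpy[iv[, 2:ny, drop = FALSE]]
  # outlet faces: one-sided gradient to the Dirichlet face value
  for (of in ctx$outlet_faces) {
    P <- Pout[[as.character(of$label)]]
    if (is.null(P)) P <- 0
    if (nrow(of$uf)) {
      pc <- pvec[of$u_cell]
      dpdx <- of$u_sign * (P - pc) / (hm / 2)   # one-sided, along +x
      u[of$uf] <- ustar[of$uf] - kappa * dpdx
    }
    if (nrow(of$vf)) {
      pc <- pvec[of$v_cell]
      dpdy <- of$v_sign * (P - pc) / (hm / 2)   # one-sided, along +y
      v[of$vf] <- vstar[of$vf] - kappa * dpdy
    }
  }
  list(u = u, v = v, p = p)
}

.outlet_fluxes <- function(ctx, u, v) {
  vapply(ctx$outlet_faces, function(of) {
    q <- 0
    if (nrow(of$uf)) q <- q + sum(of$u_sign * u[of$uf]) * ctx$hm
    if (nrow(of$vf)) q <- q + sum(of$v_sign * v[of$vf]) * ctx$hm
    q
  }, numeric(1))
}

.inlet_flux <- function(ctx, u) {
  sum(u[1, ctx$inlet_rows]) * ctx$hm
}

# flux sensitivity of each outlet to a unit pressure on each outlet
.outlet_sensitivity <- function(ctx, kappa) {
  labs <- ctx$out_labels
  n <- length(labs)
  S <- matrix(0, n, n)
  zs_u <- matrix(0, ctx$nx + 1, ctx$ny)
  zs_v <- matrix(0, ctx$nx, ctx$ny + 1)
  for (o in seq_len(n)) {
    b <- numeric(ctx$N)
    cells <- ctx$dir_cells[[as.character(labs[o])]]
    for (c0 in cells) b[c0] <- b[c0] + 2
    pvec <- as.numeric(Matrix::solve(ctx$chol, b))
    Pout <- stats::setNames(as.list(as.numeric(labs == labs[o])),
                            as.character(labs))
    fld <- .apply_projection(ctx, zs_u, zs_v, pvec, Pout, kappa)
    S[, o] <- .outlet_fluxes(ctx, fld$u, fld$v)
  }
  dimnames(S) <- list(names(ctx$outlet_faces), names(ctx$outlet_faces))
  S
}

#' Initialize a transient flow computation
#'
#' Builds the solver context (sparse Poisson factorization, face masks,
#' outlet flux sensitivities) and a zero-velocity starting state.
#'
#' @param grid a `domain_grid`.
#' @param props [fluid_properties()].
#' @param cfg [solver_config()].
#' @param waveform [inlet_waveform()].
#' @param outlet_models named list mapping outlet labels present in the grid
#'   (`"aortic_outlet"`, `"coronary_outlet"`, `"fistula_outlet"`) to outlet
#'   models ([outlet_rcr()], [outlet_resistor()], [outlet_coronary()]).
#' @return a `flow_state` object; advance it with [advance_cycle()].
#' @export
flow_init <- function(grid, props, cfg, waveform, outlet_models) {
  stopifnot(inherits(grid, "domain_grid"), inherits(props, "fluid_properties"),
            inherits(cfg, "solver_config"), inherits(waveform, "inlet_waveform"))
  nsteps <- waveform$period / cfg$dt
  if (abs(nsteps - round(nsteps)) > 1e-9) {
    stop("dt must divide the cardiac period evenly")
  }
  nsteps <- as.integer(round(nsteps))
  if (nsteps %% cfg$snapshots_per_cycle != 0) {
    stop("snapshots_per_cycle must divide the steps per cycle")
  }
  ctx <- .build_solver_ctx(grid, props, cfg)
  need <- names(ctx$outlet_faces)
  if (!all(need %in% names(outlet_models))) {
    stop(sprintf("missing outlet model(s) for: %s",
                 paste(setdiff(need, names(outlet_models)), collapse = ", ")))
  }
  models <- outlet_models[need]
  kappa <- cfg$dt / props$density
  # steady-state 0D initialization at the resistive divider of Q_mean, so
  # the warm-up does not have to ride out the Windkessel RC transients
  Rt <- vapply(models, `[[`, numeric(1), "R_total")
  Qi <- waveform$Q_mean * (1 / Rt) / sum(1 / Rt)
  net <- network_state(models)
  for (i in seq_along(models)) {
    m <- models[[i]]
    net$states[[i]] <- switch(m$kind,
      rcr = c(P_c = Qi[[i]] * m$R_d),
      resistor = numeric(0),
      coronary = c(P_ca = Qi[[i]] * (m$R_am + m$R_v), P_cim = Qi[[i]] * m$R_v)
    )
  }
  structure(
    list(
      ctx = ctx, waveform = waveform, models = models,
      net = net,
      u = matrix(0, grid$nx + 1, grid$ny),
      v = matrix(0, grid$nx, grid$ny + 1),
      t = 0, nsteps = nsteps,
      S = .outlet_sensitivity(ctx, kappa),
      kappa = kappa,
      step_count = 0L
    ),
    class = "flow_state"
  )
}

# apply boundary values to an intermediate (pre-projection) field
.apply_star_bcs <- function(ctx, ustar, vstar, Qin) {
  ustar[!ctx$u_evolve] <- 0
  vstar[!ctx$v_evolve] <- 0
  ustar[1, ctx$inlet_rows] <- ctx$inlet_shape * Qin
  for (of in ctx$outlet_faces) {       # zero-gradient intermediate outflow
    if (nrow(of$uf)) {
      inner <- cbind(ifelse(of$uf[, 1] > ctx$nx, of$uf[, 1] - 1L,
                            of$uf[, 1] + 1L), of$uf[, 2])
      ustar[of$uf] <- ustar[inner]
    }
    if (nrow(of$vf)) {
      inner <- cbind(of$vf[, 1], ifelse(of$vf[, 2] > ctx$ny, of$vf[, 2] - 1L,
                                        of$vf[, 2] + 1L))
      vstar[of$vf] <- vstar[inner]
    }
  }
  list(u = ustar, v = vstar)
}

# project an intermediate field onto the divergence-free space with the
# 0D-coupled outlet pressures solved exactly (affine coupling)
.project_coupled <- function(state, ustar, vstar, aff) {
  ctx <- state$ctx
  kappa <- state$kappa
  labs <- names(ctx$outlet_faces)
  a <- vapply(aff, `[[`, numeric(1), "a")
  bb <- vapply(aff, `[[`, numeric(1), "b")
  div <- .divergence(ctx, ustar, vstar)
  rhs <- -(ctx$hm^2) * div[ctx$fluid] / kappa
  p0 <- as.numeric(Matrix::solve(ctx$chol, rhs))
  zeroP <- stats::setNames(as.list(rep(0, length(labs))), names(ctx$dir_cells))
  base <- .apply_projection(ctx, ustar, vstar, p0, zeroP, kappa)
  Q0 <- .outlet_fluxes(ctx, base$u, base$v)
  A <- diag(bb, nrow = length(bb)) - state$S
  P <- as.numeric(solve(A, Q0 - a))
  names(P) <- labs
  pvec <- p0
  for (o in seq_along(labs)) {
    if (P[o] == 0) next
    b <- numeric(ctx$N)
    for (c0 in ctx$dir_cells[[o]]) b[c0] <- b[c0] + 2 * P[o]
    pvec <- pvec + as.numeric(Matrix::solve(ctx$chol, b))
  }
  Pout <- stats::setNames(as.list(P), names(ctx$dir_cells))
  fld <- .apply_projection(ctx, ustar, vstar, pvec, Pout, kappa)
  Qf <- .outlet_fluxes(ctx, fld$u, fld$v)
  list(u = fld$u, v = fld$v, p = fld$p, P = P, Qf = Qf, a = a, b = bb)
}

# one SSP-RK2 (Heun) time step with a projection per stage; returns the
# updated state plus the snapshot fields
.flow_step <- function(state) {
  ctx <- state$ctx
  cfg <- ctx$cfg
  dt <- cfg$dt
  t_new <- state$t + dt
  Qin <- evaluate_inlet_flow(state$waveform, t_new)

  # one backward-Euler affine relation per outlet, shared by both stages
  labs <- names(ctx$outlet_faces)
  aff <- lapply(seq_along(labs), function(i) {
    .outlet_affine(state$models[[i]], state$net$states[[i]], dt, t_new)
  })

  F1 <- .momentum_rhs(ctx, state$u, state$v)
  s1 <- .apply_star_bcs(ctx, state$u + dt * F1$Fu, state$v + dt * F1$Fv, Qin)
  .check_divergence_guard(s1, t_new)
  st1 <- .project_coupled(state, s1$u, s1$v, aff)

  F2 <- .momentum_rhs(ctx, st1$u, st1$v)
  s2 <- .apply_star_bcs(
    ctx,
    0.5 * (state$u + st1$u + dt * F2$Fu),
    0.5 * (state$v + st1$v + dt * F2$Fv),
    Qin
  )
  .check_divergence_guard(s2, t_new)
  fin <- .project_coupled(state, s2$u, s2$v, aff)

  # sub-iteration residual check (the affine coupling is exact, so this
  # converges at the first pass; a violation indicates a solver fault)
  scale <- max(abs(Qin), 1e-300)
  res <- sqrt(mean((fin$Qf - (fin$a + fin$b * fin$P))^2)) / scale
  if (res > cfg$rms_residual_tol && cfg$max_subiterations > 1) {
    stop(sprintf("pressure-coupling residual %.3g exceeds tolerance %.3g",
                 res, cfg$rms_residual_tol))
  }

  # advance 0D states at the realized nodal pressures
  for (i in seq_along(labs)) {
    state$net$states[[i]] <- aff[[i]]$advance(fin$P[i])
  }
  state$net$t <- t_new

  state$u <- fin$u; state$v <- fin$v
  state$t <- t_new
  state$step_count <- state$step_count + 1L

  list(state = state,
       snap = list(u = fin$u, v = fin$v, p = fin$p, t = t_new,
                   Q_in = Qin, Q_out = fin$Qf, P_out = fin$P,
                   residual = res, subiterations = 1L))
}

.check_divergence_guard <- function(s, t_new) {
  vmax <- max(abs(s$u), abs(s$v))
  if (!is.finite(vmax) || vmax > 100) {
    stop(sprintf("flow solver diverged at t = %.4f s (|u|max = %.3g m/s)",
                 t_new, vmax))
  }
}

#' Advance the flow one cardiac cycle
#'
#' Runs one period of BDF2 projection steps with the pulsatile inlet and the
#' 0D-coupled outlets, returning the updated state and the cycle's snapshots.
#'
#' @param grid a `domain_grid` (must match the one used in [flow_init()]).
#' @param props,cfg,waveform,outlet_models as in [flow_init()]; used to build
#'   the state when `state` is `NULL`.
#' @param state a `flow_state` from [flow_init()] or a previous call, or
#'   `NULL` to initialize.
#' @return list with `state` and `cycle`, a `flow_cycle` object: snapshots
#'   (`u`, `v`, `p`, time stamp, inlet/outlet fluxes) at
#'   `snapshots_per_cycle` instants.
#' @export
advance_cycle <- function(grid, props, cfg, waveform, outlet_models,
                          state = NULL) {
  if (is.null(state)) {
    state <- flow_init(grid, props, cfg, waveform, outlet_models)
  }
  keep_every <- state$nsteps %/% state$ctx$cfg$snapshots_per_cycle
  snaps <- vector("list", state$ctx$cfg$snapshots_per_cycle)
  ks <- 0L
  for (k in seq_len(state$nsteps)) {
    stepped <- .flow_step(state)
    state <- stepped$state
    if (k %% keep_every == 0L) {
      ks <- ks + 1L
      snaps[[ks]] <- stepped$snap
    }
  }
  cycle <- structure(
    list(snapshots = snaps, period = state$waveform$period,
         dt = state$ctx$cfg$dt, grid_dims = c(state$ctx$nx, state$ctx$ny)),
    class = "flow_cycle"
  )
  list(state = state, cycle = cycle)
}

#' Cycle-to-cycle periodic convergence check
#'
#' RMS relative difference of the velocity fields at matching phases of two
#' consecutive cycles; the flow is declared periodic below `tol`.
#'
#' @param prev_cycle,this_cycle `flow_cycle` objects with equal snapshot
#'   counts.
#' @param tol relative RMS threshold.
#' @return list with `converged` and the `metric`.
#' @export
check_periodic_convergence <- function(prev_cycle, this_cycle, tol = 5e-3) {
  n1 <- length(prev_cycle$snapshots); n2 <- length(this_cycle$snapshots)
  if (n1 != n2) stop("cycles have mismatched snapshot counts")
  num <- 0; den <- 0
  for (k in seq_len(n1)) {
    a <- prev_cycle$snapshots[[k]]; b <- this_cycle$snapshots[[k]]
    num <- num + sum((b$u - a$u)^2) + sum((b$v - a$v)^2)
    den <- den + sum(b$u^2) + sum(b$v^2)
  }
  metric <- if (den > 0) sqrt(num / den) else 0
  list(converged = metric < tol, metric = metric)
}

#' Run the flow to a periodic state
#'
#' Advances whole cardiac cycles until [check_periodic_convergence()] passes
#' or `n_warmup_cycles` is reached, and returns the last (periodic) cycle.
#'
#' @inheritParams flow_init
#' @return list with the final `state`, the periodic `cycle`, the
#'   per-cycle convergence `history` and the `converged` flag.
#' @export
simulate_flow <- function(grid, props, cfg, waveform, outlet_models) {
  state <- flow_init(grid, props, cfg, waveform, outlet_models)
  prev <- NULL
  history <- numeric(0)
  converged <- FALSE
  for (cyc in seq_len(cfg$n_warmup_cycles)) {
    out <- advance_cycle(grid, props, cfg, waveform, outlet_models, state)
    state <- out$state
    if (!is.null(prev)) {
      chk <- check_periodic_convergence(prev, out$cycle, cfg$periodic_tol)
      history <- c(history, chk$metric)
      if (chk$converged) {
        converged <- TRUE
        prev <- out$cycle
        break
      }
    }
    prev <- out$cycle
  }
  list(state = state, cycle = prev, history = history, converged = converged)
}

#' Wall shear stress series from a periodic cycle
#'
#' One-sided reconstruction of the tangential velocity gradient at every
#' wall face with a fluid neighbour: `tau = mu * 2 u_t1 / h` with `u_t1` the
#' tangential velocity at the first cell center. This half-cell flux is the
#' discrete wall stress consistent with the solver's ghost-reflection
#' no-slip (it is exact for the discrete fully developed channel solution).
#' The sign follows a fixed per-face tangent convention (tangent +x for
#' horizontal walls, +y for vertical walls; the sign flips with the wall
#' normal direction, so opposite channel walls carry opposite signs).
#'
#' @param cycle a `flow_cycle`.
#' @param grid the `domain_grid` the cycle was computed on.
#' @param props [fluid_properties()].
#' @return object of class `wall_shear_series`: `tau` (faces x times, Pa),
#'   `times` (s), and per-face metadata `face_info` (position mm, region of
#'   the adjacent fluid cell, face measure mm^2).
#' @export
extract_wall_shear <- function(cycle, grid, props) {
  stopifnot(inherits(cycle, "flow_cycle"), inherits(grid, "domain_grid"))
  nx <- grid$nx; ny <- grid$ny
  hm <- grid$h * 1e-3
  mu <- props$dynamic_viscosity
  fl <- grid$fluid

  faces <- list()
  # horizontal walls (v-type WALL): tangential u, normal +/- y
  vw <- which(grid$v_type == FACE_WALL, arr.ind = TRUE)
  for (k in seq_len(nrow(vw))) {
    i <- vw[k, 1]; j <- vw[k, 2]
    above <- j <= ny && fl[i, j]
    below <- j >= 2 && fl[i, j - 1]
    if (above == below) {
      if (!above) stop("wall face with no adjacent fluid cell (mislabelled grid)")
      next  # interior wall face cannot have fluid on both sides
    }
    if (above) {
      c1 <- c(i, j); s <- 1
    } else {
      c1 <- c(i, j - 1); s <- -1
    }
    faces[[length(faces) + 1]] <- list(
      kind = "h", c1 = c1, s = s,
      x = (i - 0.5) * grid$h, y = (j - 1) * grid$h,
      region = grid$region[c1[1], c1[2]]
    )
  }
  # vertical walls (u-type WALL): tangential v, normal +/- x
  uw <- which(grid$u_type == FACE_WALL, arr.ind = TRUE)
  for (k in seq_len(nrow(uw))) {
    i <- uw[k, 1]; j <- uw[k, 2]
    right <- i <= nx && fl[i, j]
    left <- i >= 2 && fl[i - 1, j]
    if (right == left) {
      if (!right) stop("wall face with no adjacent fluid cell (mislabelled grid)")
      next
    }
    if (right) {
      c1 <- c(i, j); s <- 1
    } else {
      c1 <- c(i - 1, j); s <- -1
    }
    faces[[length(faces) + 1]] <- list(
      kind = "v", c1 = c1, s = s,
      x = (i - 1) * grid$h, y = (j - 0.5) * grid$h,
      region = grid$region[c1[1], c1[2]]
    )
  }
  nf <- length(faces)
  nt <- length(cycle$snapshots)
  tau <- matrix(0, nf, nt)
  for (kt in seq_len(nt)) {
    sn <- cycle$snapshots[[kt]]
    ucc <- 0.5 * (sn$u[-(nx + 1), , drop = FALSE] + sn$u[-1, , drop = FALSE])
    vcc <- 0.5 * (sn$v[, -(ny + 1), drop = FALSE] + sn$v[, -1, drop = FALSE])
    for (kf in seq_len(nf)) {
      f <- faces[[kf]]
      cc <- if (f$kind == "h") ucc else vcc
      t1 <- cc[f$c1[1], f$c1[2]]
      tau[kf, kt] <- f$s * mu * 2 * t1 / hm
    }
  }
  info <- data.frame(
    x = vapply(faces, `[[`, numeric(1), "x"),
    y = vapply(faces, `[[`, numeric(1), "y"),
    region = REGION_LEVELS[vapply(faces, `[[`, integer(1), "region")],
    measure = rep(grid$h, nf)    # mm x 1 mm depth = mm^2
  )
  structure(
    list(tau = tau, times = vapply(cycle$snapshots, `[[`, numeric(1), "t"),
         face_info = info, period = cycle$period),
    class = "wall_shear_series"
  )
}
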