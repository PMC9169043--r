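# Two-fluid blood-stasis (washout) simulation. The "old" blood initially
# fills the whole domain; "new" blood with identical material properties and
# zero surface tension enters at the inlet. Under those settings two-fluid
# volume-of-fluid transport reduces exactly to conservative passive-scalar
# advection of the old-blood fraction alpha, which is what is solved here:
# the converged periodic flow cycle is replayed and alpha is advected with a
# van Leer flux-limited scheme.

#' Initialize the two-fluid (old/new blood) fraction field
#'
#' Every fluid cell starts as old blood (`alpha = 1`); the inlet carries an
#' incoming old-blood fraction of 0 (new blood fraction 1).
#'
#' @param grid a `domain_grid`.
#' @return object of class `fraction_field` with `alpha` (matrix, `NA` in
#'   solid cells) and the time stamp `t`.
#' @export
initialize_two_fluid <- function(grid) {
  stopifnot(inherits(grid, "domain_grid"))
  alpha <- matrix(NA_real_, grid$nx, grid$ny)
  alpha[grid$fluid] <- 1
  structure(list(alpha = alpha, t = 0), class = "fraction_field")
}

#' Advect the old-blood fraction through one cardiac cycle
#'
#' Conservative flux-limited (van Leer) advection of `alpha` using the face
#' velocities of the periodic flow cycle; walls carry zero flux, the inlet
#' carries incoming `alpha = 0`, outlets are upwinded (reverse inflow, if
#' any, also carries `alpha = 0`). Boundedness is asserted to 1e-6 every
#' step.
#'
#' @param field a `fraction_field`.
#' @param cycle a `flow_cycle` whose snapshots cover one period at the
#'   transport step.
#' @param grid the `domain_grid`.
#' @param cfg [solver_config()] (supplies the step size via the cycle).
#' @return the advanced `fraction_field`.
#' @export
advance_fraction <- function(field, cycle, grid, cfg = NULL) {
  stopifnot(inherits(field, "fraction_field"), inherits(cycle, "flow_cycle"))
  nx <- grid$nx; ny <- grid$ny
  hm <- grid$h * 1e-3
  nsnap <- length(cycle$snapshots)
  dt <- cycle$period / nsnap
  alpha <- field$alpha
  a <- alpha
  a[!grid$fluid] <- 0
  fl <- grid$fluid

  # face openness masks (zero flux through walls / inactive faces)
  u_open <- grid$u_type != FACE_WALL & grid$u_type != FACE_INACTIVE
  v_open <- grid$v_type != FACE_WALL & grid$v_type != FACE_INACTIVE

  for (k in seq_len(nsnap)) {
    sn <- cycle$snapshots[[k]]
    u <- sn$u; v <- sn$v
    u[!u_open] <- 0
    v[!v_open] <- 0

    # sub-step so the combined advective CFL stays below 0.45: the unsplit
    # 2D update with 1D limited face values is bounded only under a CFL
    # roughly half the 1D bound
    cfl <- (max(abs(u)) + max(abs(v))) * dt / hm
    m <- max(1L, ceiling(cfl / 0.45))
    dts <- dt / m
    for (s in seq_len(m)) {
      # x faces: pad alpha with ghost columns carrying the boundary inflow
      # value 0 (new blood); outflow upwinds from the interior
      ax <- rbind(0, a, 0)                                # (nx+2) x ny
      aface <- .muscl_dim1(ax, u)                         # (nx+1) x ny
      Fx <- u * aface
      ay <- cbind(0, a, 0)                                # nx x (ny+2)
      afy <- .muscl_dim2(ay, v)                           # nx x (ny+1)
      Fy <- v * afy

      a <- a - (dts / hm) * (Fx[-1, , drop = FALSE] - Fx[-(nx + 1), , drop = FALSE] +
                               Fy[, -1, drop = FALSE] - Fy[, -(ny + 1), drop = FALSE])
      a[!fl] <- 0
      lo <- min(a[fl]); hi <- max(a[fl])
      if (lo < -1e-6 || hi > 1 + 1e-6) {
        stop(sprintf(
          "fraction boundedness violated (min %.3g, max %.3g): limiter fault",
          lo, hi
        ))
      }
    }
  }
  alpha[fl] <- a[fl]
  structure(list(alpha = alpha, t = field$t + cycle$period),
            class = "fraction_field")
}

#' Old blood volume fraction of the fistula region
#'
#' `OBVF = 100 * sum(alpha * cell measure) / fistula measure` over the
#' fistula region (which includes the terminal aneurysm when present).
#'
#' @param field a `fraction_field`.
#' @param grid the `domain_grid`.
#' @param region region whose residue is quantified (default `"fistula"`).
#' @return OBVF in percent.
#' @export
compute_obvf <- function(field, grid, region = "fistula") {
  stopifnot(inherits(field, "fraction_field"))
  codes <- switch(region,
    fistula = c(2L, 3L),
    aorta = 1L,
    aneurysm = 3L,
    stop(sprintf("unknown region tag '%s'", region))
  )
  sel <- !is.na(grid$region) & grid$region %in% codes
  if (!any(sel)) stop(sprintf("region '%s' is empty", region))
  100 * sum(field$alpha[sel]) / sum(sel)
}

#' Washout convergence check
#'
#' The washout is converged when the OBVF dropped by less than one absolute
#' percentage point over the trailing 10 cardiac cycles. Histories shorter
#' than 11 cycles are reported not converged (not an error).
#'
#' @param history numeric vector of per-cycle OBVF values (percent),
#'   `history[1]` being cycle 0 (always 100).
#' @param window trailing window in cycles.
#' @param drop_tol maximum OBVF drop (percentage points) over the window.
#' @return list with `converged` and the trailing `drop` (NA when the
#'   history is too short).
#' @export
check_washout_convergence <- function(history, window = 10, drop_tol = 1) {
  n <- length(history)
  if (n < window + 1) {
    return(list(converged = FALSE, drop = NA_real_))
  }
  drop <- history[n - window] - history[n]
  list(converged = drop < drop_tol, drop = drop)
}

#' Run the washout to convergence
#'
#' Replays the periodic flow cycle, advecting the old-blood fraction and
#' recording the fistula OBVF each cardiac cycle, until the 1-point/10-cycle
#' criterion is met or `max_cycles` is reached (with a warning, mirroring the
#' 10-60 cycle envelope such washouts need).
#'
#' @param grid a `domain_grid`.
#' @param cycle the converged periodic `flow_cycle`.
#' @param max_cycles cycle cap.
#' @param cfg optional [solver_config()] passed through to
#'   [advance_fraction()].
#' @return list with `history` (class `washout_history`: per-cycle OBVF %,
#'   cycle 0 first), the final `field`, `cycles` run and `converged`.
#' @export
run_washout <- function(grid, cycle, max_cycles = 60, cfg = NULL) {
  field <- initialize_two_fluid(grid)
  history <- compute_obvf(field, grid)
  converged <- FALSE
  cycles <- 0L
  while (cycles < max_cycles) {
    field <- advance_fraction(field, cycle, grid, cfg)
    cycles <- cycles + 1L
    history <- c(history, compute_obvf(field, grid))
    chk <- check_washout_convergence(history)
    if (chk$converged) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "washout not converged after %d cycles (trailing drop %.2f points)",
      cycles, check_washout_convergence(history)$drop
    ))
  }
  structure(
    list(history = structure(history, class = "washout_history"),
         field = field, cycles = cycles, converged = converged),
    class = "washout_result"
  )
}
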