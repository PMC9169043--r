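# Lumped-parameter (0D) outlet models and their coupling to a common
# upstream pressure node. All models are advanced with backward Euler; for
# coupling, each outlet exposes its backward-Euler step as an affine relation
# Q = a + b * P in the unknown nodal pressure P, so the common node is solved
# exactly at every step (no fixed-point iteration).

#' Three-element Windkessel (RCR) outlet parameters
#'
#' The proximal/distal split follows the usual aortic convention:
#' `R_p = 0.09 R_total`, `R_d = 0.91 R_total`. The default compliance is
#' 0.001 cm^5/dyne expressed in SI (1.0e-8 m^3/Pa; conversion factor 1e-5).
#'
#' @param R_total total resistance (Pa s/m^3).
#' @param C compliance (m^3/Pa).
#' @param R_p_fraction proximal share of `R_total`.
#' @return an object of class `outlet_rcr`.
#' @export
outlet_rcr <- function(R_total, C = 1.0e-8, R_p_fraction = 0.09) {
  stopifnot(R_total > 0, C > 0, R_p_fraction > 0, R_p_fraction < 1)
  structure(
    list(
      kind = "rcr", R_total = R_total,
      R_p = R_p_fraction * R_total, R_d = (1 - R_p_fraction) * R_total,
      C = C
    ),
    class = c("outlet_rcr", "outlet_model")
  )
}

#' Pure resistive outlet
#'
#' @param R resistance (Pa s/m^3).
#' @return an object of class `outlet_resistor`.
#' @export
outlet_resistor <- function(R) {
  stopifnot(R > 0)
  structure(list(kind = "resistor", R_total = R),
            class = c("outlet_resistor", "outlet_model"))
}

#' Coronary lumped-parameter network (LPN) outlet parameters
#'
#' Two-compliance coronary outlet: arterial resistance `R_a`, arterial
#' microcirculation resistance `R_am`, venous resistance `R_v` (summing to
#' `R_total`), arterial compliance `C_a` to ground and intramyocardial
#' compliance `C_im` referenced to the intramyocardial pressure `P_im(t)`,
#' which squeezes the microcirculation during systole. `P_im` is a
#' sin^2-shaped systolic pulse of height `p_im_peak * p_im_scale`
#' (`p_im_scale` 1.0 for left, 0.5 for right coronary territory).
#'
#' @param R_total total resistance (Pa s/m^3).
#' @param fractions shares of `R_total` assigned to `R_a`, `R_am`, `R_v`.
#' @param C_a,C_im compliances (m^3/Pa).
#' @param p_im_peak peak intramyocardial pressure (Pa).
#' @param p_im_scale territory scaling of the intramyocardial pulse.
#' @param period,systolic_fraction timing of the intramyocardial pulse (s, -).
#' @return an object of class `outlet_coronary`.
#' @export
outlet_coronary <- function(R_total,
                            fractions = c(R_a = 0.32, R_am = 0.52, R_v = 0.16),
                            C_a = 1.0e-10, C_im = 1.0e-9,
                            p_im_peak = 16e3, p_im_scale = 1.0,
                            period = 1.0, systolic_fraction = 0.35) {
  stopifnot(R_total > 0, C_a > 0, C_im > 0, length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("coronary resistance fractions must sum to 1 (R_a + R_am + R_v = R_total)")
  }
  structure(
    list(
      kind = "coronary", R_total = R_total,
      R_a = fractions[[1]] * R_total,
      R_am = fractions[[2]] * R_total,
      R_v = fractions[[3]] * R_total,
      C_a = C_a, C_im = C_im,
      p_im_peak = p_im_peak, p_im_scale = p_im_scale,
      p_im_period = period, p_im_systolic_fraction = systolic_fraction
    ),
    class = c("outlet_coronary", "outlet_model")
  )
}

#' Intramyocardial pressure of a coronary outlet at time t
#'
#' @param p an [outlet_coronary()].
#' @param t time(s), s. Vectorized.
#' @return pressure (Pa).
#' @export
coronary_p_im <- function(p, t) {
  tau <- t %% p$p_im_period
  ts <- p$p_im_systolic_fraction * p$p_im_period
  out <- numeric(length(tau))
  sys <- tau < ts
  out[sys] <- p$p_im_peak * p$p_im_scale * sin(pi * tau[sys] / ts)^2
  out
}

#' Initial state of a set of 0D outlets
#'
#' @param outlets list of outlet models.
#' @param t initial time (s).
#' @param P0 initial internal pressure(s) (Pa), recycled across outlets.
#' @return an object of class `network_state`.
#' @export
network_state <- function(outlets, t = 0, P0 = 0) {
  P0 <- rep(P0, length.out = length(outlets))
  states <- lapply(seq_along(outlets), function(i) {
    switch(outlets[[i]]$kind,
      rcr = c(P_c = P0[i]),
      resistor = numeric(0),
      coronary = c(P_ca = P0[i], P_cim = P0[i]),
      stop("unknown outlet kind")
    )
  })
  structure(list(states = states, t = t), class = "network_state")
}

# --- backward-Euler affine relations Q = a + b * P per outlet -------------

# returns list(a, b, advance(P) -> new state vector)
.outlet_affine <- function(p, state, dt, t_new) {
  switch(p$kind,
    resistor = list(
      a = 0, b = 1 / p$R_total,
      advance = function(P) numeric(0)
    ),
    rcr = {
      beta <- 1 + dt / (p$R_d * p$C)
      denom <- p$R_p + dt / (p$C * beta)
      P_c <- state[["P_c"]]
      list(
        a = -(P_c / beta) / denom, b = 1 / denom,
        advance = function(P) {
          Q <- (unname(P) - P_c / beta) / denom
          c(P_c = (P_c + dt * Q / p$C) / beta)
        }
      )
    },
    coronary = {
      # BE for  C_a P1' = Q - (P1-P2)/R_am
      #         C_im P2' = (P1-P2)/R_am - P2/R_v + C_im dP_im/dt
      # with Q = (P - P1)/R_a; solve the 2x2 for P1 as alpha + gamma*Q
      dpim <- coronary_p_im(p, t_new) - coronary_p_im(p, t_new - dt)
      A11 <- p$C_a / dt + 1 / p$R_am
      A12 <- -1 / p$R_am
      A22 <- p$C_im / dt + 1 / p$R_am + 1 / p$R_v
      det <- A11 * A22 - A12 * A12
      r1q <- p$C_a * state[["P_ca"]] / dt          # + Q
      r2 <- p$C_im * state[["P_cim"]] / dt + p$C_im * dpim / dt
      # P1 = (A22*(r1q + Q) - A12*r2)/det = alpha + gamma*Q
      alpha <- (A22 * r1q - A12 * r2) / det
      gamma <- A22 / det
      denom <- p$R_a + gamma
      list(
        a = -alpha / denom, b = 1 / denom,
        advance = function(P) {
          Q <- (unname(P) - alpha) / denom
          P1 <- alpha + gamma * Q
          P2 <- (A12 * (r1q + Q) - A11 * r2) / (-det) # solve second row
          c(P_ca = P1, P_cim = P2)
        }
      )
    },
    stop("unknown outlet kind")
  )
}

#' Advance a Windkessel RCR outlet one implicit step
#'
#' Backward-Euler step of `dP_c/dt = (Q_in - P_c/R_d)/C`; the returned outlet
#' pressure is `P = P_c + Q_in * R_p`.
#'
#' @param p an [outlet_rcr()].
#' @param state named numeric with element `P_c` (Pa), or a scalar.
#' @param Q_in inflow (m^3/s).
#' @param dt time step (s); must be positive.
#' @return list with `state` (new `P_c`) and `pressure` (Pa).
#' @export
windkessel_step <- function(p, state, Q_in, dt) {
  stopifnot(inherits(p, "outlet_rcr"))
  if (dt <= 0) stop("dt must be positive")
  P_c <- if (is.list(state)) state$P_c else unname(state[1])
  beta <- 1 + dt / (p$R_d * p$C)
  P_c_new <- (P_c + dt * Q_in / p$C) / beta
  list(state = c(P_c = P_c_new), pressure = P_c_new + Q_in * p$R_p)
}

#' Advance a coronary LPN outlet one implicit step
#'
#' Backward-Euler step of the two-compliance coronary circuit with the flow
#' `Q_in` prescribed; the intramyocardial pressure rate forces the `C_im`
#' state. Returns the proximal pressure `P = P_ca + Q_in * R_a`.
#'
#' @param p an [outlet_coronary()].
#' @param state named numeric with elements `P_ca`, `P_cim` (Pa).
#' @param Q_in inflow (m^3/s).
#' @param dt time step (s); must be positive.
#' @param t time at the end of the step (s); defaults to `dt` steps from 0
#'   being untracked, i.e. `P_im` evaluated at `t` and `t - dt`.
#' @return list with `state` (new `P_ca`, `P_cim`) and `pressure` (Pa).
#' @export
coronary_lpn_step <- function(p, state, Q_in, dt, t = dt) {
  stopifnot(inherits(p, "outlet_coronary"))
  if (dt <= 0) stop("dt must be positive")
  dpim <- coronary_p_im(p, t) - coronary_p_im(p, t - dt)
  A11 <- p$C_a / dt + 1 / p$R_am
  A12 <- -1 / p$R_am
  A22 <- p$C_im / dt + 1 / p$R_am + 1 / p$R_v
  det <- A11 * A22 - A12 * A12
  r1 <- p$C_a * state[["P_ca"]] / dt + Q_in
  r2 <- p$C_im * state[["P_cim"]] / dt + p$C_im * dpim / dt
  P1 <- (A22 * r1 - A12 * r2) / det
  P2 <- (A11 * r2 - A12 * r1) / det
  list(state = c(P_ca = P1, P_cim = P2), pressure = P1 + Q_in * p$R_a)
}

#' Cycle-averaged flow split across 0D outlets on a common node
#'
#' Feeds the inlet waveform into a single pressure node from which every
#' outlet model drains, advances the coupled network with backward Euler
#' until periodic (cycle-to-cycle state change below `cycle_tol`), and
#' returns the cycle-averaged flow fraction through each outlet.
#'
#' @param waveform an [inlet_waveform()].
#' @param outlets list of outlet models ([outlet_rcr()], [outlet_resistor()],
#'   [outlet_coronary()]); at least two.
#' @param dt integration step (s).
#' @param cycle_tol relative cycle-to-cycle state change declaring
#'   periodicity.
#' @param max_cycles cap on cycles before giving up.
#' @return list with `fractions` (named if `outlets` is named; sums to 1),
#'   `flows` (cycle-averaged m^3/s), `cycles` used and the convergence
#'   `residuals` per cycle.
#' @export
solve_0d_flow_split <- function(waveform, outlets,
                                dt = waveform$period / 1000,
                                cycle_tol = 1e-3, max_cycles = 100) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  if (length(outlets) < 2) stop("need at least two outlets to split flow")
  n <- length(outlets)
  nsteps <- round(waveform$period / dt)
  dt <- waveform$period / nsteps
  st <- network_state(outlets)
  residuals <- numeric(0)
  for (cyc in seq_len(max_cycles)) {
    prev <- unlist(st$states)
    q_acc <- numeric(n)
    for (k in seq_len(nsteps)) {
      t_new <- st$t + dt
      aff <- lapply(seq_len(n), function(i) {
        .outlet_affine(outlets[[i]], st$states[[i]], dt, t_new)
      })
      a_sum <- sum(vapply(aff, `[[`, numeric(1), "a"))
      b_sum <- sum(vapply(aff, `[[`, numeric(1), "b"))
      Q_in <- evaluate_inlet_flow(waveform, t_new)
      P <- (Q_in - a_sum) / b_sum
      for (i in seq_len(n)) {
        q_acc[i] <- q_acc[i] + (aff[[i]]$a + aff[[i]]$b * P) * dt
        st$states[[i]] <- aff[[i]]$advance(P)
      }
      st$t <- t_new
    }
    cur <- unlist(st$states)
    denom <- max(sqrt(mean(cur^2)), 1e-300)
    res <- if (length(cur)) sqrt(mean((cur - prev)^2)) / denom else 0
    residuals <- c(residuals, res)
    if (res < cycle_tol) {
      flows <- q_acc / waveform$period
      fr <- flows / sum(flows)
      names(fr) <- names(flows) <- names(outlets)
      return(list(fractions = fr, flows = flows, cycles = cyc,
                  residuals = residuals))
    }
  }
  stop(sprintf(
    "0D network not periodic after %d cycles; last residuals: %s",
    max_cycles, paste(signif(utils::tail(residuals, 5), 3), collapse = ", ")
  ))
}
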