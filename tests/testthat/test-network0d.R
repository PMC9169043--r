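test_that("inlet waveform is periodic, non-negative and mean-preserving", {
  w <- inlet_waveform(Q_mean = 3e-4)
  t <- seq(0, 1, by = 1e-4)
  expect_equal(evaluate_inlet_flow(w, t), evaluate_inlet_flow(w, t + 1.0))
  expect_true(all(evaluate_inlet_flow(w, t) >= 0))
  # quadrature oracle for the cycle mean
  q <- evaluate_inlet_flow(w, (seq_len(2e4) - 0.5) / 2e4)
  expect_equal(mean(q), w$Q_mean, tolerance = 1e-3)
  # degenerate constant waveform
  wc <- inlet_waveform(Q_mean = 3e-4, pulsatility = 1)
  expect_equal(evaluate_inlet_flow(wc, c(0.1, 0.5, 0.93)), rep(3e-4, 3))
  # continuity at the systole/diastole transition
  ts <- w$systolic_fraction
  expect_equal(evaluate_inlet_flow(w, ts - 1e-9),
               evaluate_inlet_flow(w, ts + 1e-9), tolerance = 1e-6)
  expect_error(inlet_waveform(1e-4, pulsatility = 10), "pulsatility")
})

test_that("Windkessel RCR has the prescribed split and closed-form behaviour", {
  p <- outlet_rcr(2.3171e8)
  expect_equal(p$R_p + p$R_d, p$R_total, tolerance = 1e-12)
  expect_equal(p$R_p / p$R_total, 0.09)
  expect_equal(p$C, 1.0e-8)           # 0.001 cm^5/dyne in m^3/Pa
  expect_error(windkessel_step(p, c(P_c = 0), 1e-4, dt = 0), "dt")

  # constant flow to steady state: P -> Q * R_total
  st <- c(P_c = 0); Q <- 2e-4
  for (k in 1:5000) { r <- windkessel_step(p, st, Q, 0.01); st <- r$state }
  expect_equal(r$pressure, Q * p$R_total, tolerance = 1e-6)

  # zero-flow decay from P_c0: time constant R_d * C
  st <- c(P_c = 1e4); dt <- 1e-3
  tr <- numeric(2000)
  for (k in seq_along(tr)) { st <- windkessel_step(p, st, 0, dt)$state; tr[k] <- st }
  tau_fit <- -1 / stats::coef(stats::lm(log(tr) ~ I(seq_along(tr) * dt)))[[2]]
  expect_equal(tau_fit, p$R_d * p$C, tolerance = 5e-3)

  # implicit step is unconditionally stable: dt up to the period
  st <- c(P_c = 1e4)
  for (k in 1:100) st <- windkessel_step(p, st, 2e-4 * sin(k), 1.0)$state
  expect_true(is.finite(st) && abs(st) < 1e7)
})

test_that("halving dt changes the periodic Windkessel trace by < 0.2% RMS", {
  p <- outlet_rcr(2.3171e8)
  trace <- function(dt) {
    n <- round(1 / dt)
    st <- c(P_c = 2e-4 * p$R_d)
    out <- numeric(n)
    for (cyc in 1:8) {
      for (k in 1:n) {
        Q <- 2e-4 * (1 + sin(2 * pi * k * dt))
        r <- windkessel_step(p, st, Q, dt)
        st <- r$state
        out[k] <- r$pressure
      }
    }
    out
  }
  a <- trace(1e-3)
  b <- trace(5e-4)[seq(2, 2000, by = 2)]
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.002)
})

test_that("coronary LPN matches its steady-state algebra and P_im coupling", {
  pc <- outlet_coronary(1e9, p_im_scale = 0)
  expect_equal(pc$R_a + pc$R_am + pc$R_v, pc$R_total, tolerance = 1e-9)
  expect_error(outlet_coronary(1e9, fractions = c(0.5, 0.2, 0.2)), "sum to 1")

  # steady response of the stated ODEs: algebraic solve gives P = Q * sum(R)
  # (with constant P_im the intramyocardial capacitor carries no current)
  st <- c(P_ca = 0, P_cim = 0); Q <- 2e-4
  for (k in 1:40000) { r <- coronary_lpn_step(pc, st, Q, 0.01, t = k * 0.01); st <- r$state }
  expect_equal(r$pressure, Q * pc$R_total, tolerance = 1e-6)
  expect_equal(st[["P_ca"]], Q * (pc$R_am + pc$R_v), tolerance = 1e-6)
  expect_equal(st[["P_cim"]], Q * pc$R_v, tolerance = 1e-6)

  # rising intramyocardial pressure at fixed inflow raises proximal pressure
  ph <- outlet_coronary(1e9, p_im_scale = 1)
  st <- c(P_ca = Q * (ph$R_am + ph$R_v), P_cim = Q * ph$R_v)
  dt <- 1e-3
  ts <- ph$p_im_systolic_fraction / 2          # mid systolic upstroke
  steps <- seq(0.05, ts, by = dt)
  pr <- numeric(length(steps))
  for (i in seq_along(steps)) {
    r <- coronary_lpn_step(ph, st, Q, dt, t = steps[i])
    st <- r$state
    pr[i] <- r$pressure
  }
  expect_true(all(diff(pr[-(1:5)]) > 0))
})

test_that("0D flow split reproduces resistive dividers and conserves flow", {
  w <- inlet_waveform(Q_mean = 1e-4, pulsatility = 1)
  r <- solve_0d_flow_split(w, list(a = outlet_resistor(1e8),
                                   b = outlet_resistor(9e8)))
  expect_equal(unname(r$fractions), c(0.9, 0.1), tolerance = 1e-9)

  # n identical outlets split evenly
  outl <- replicate(4, outlet_rcr(4e8), simplify = FALSE)
  wp <- inlet_waveform(Q_mean = 1e-4)
  r4 <- solve_0d_flow_split(wp, outl)
  expect_equal(unname(r4$fractions), rep(0.25, 4), tolerance = 1e-6)
  # conservation: cycle-averaged outlet flows sum to the inlet mean
  expect_equal(sum(r4$flows), wp$Q_mean, tolerance = 5e-3)

  expect_error(solve_0d_flow_split(w, list(outlet_resistor(1e8))),
               "at least two")
})
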