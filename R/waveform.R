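# Pulsatile inlet waveform: half-sine systolic ejection over a plateau
# diastolic baseline, renormalized so the cycle mean equals Q_mean.

#' Pulsatile inlet flow waveform
#'
#' Parametric cardiac inflow: a half-sine systolic pulse of duration
#' `systolic_fraction * period` on top of a diastolic plateau, scaled so that
#' the cycle average equals `Q_mean` and the peak-to-mean ratio equals
#' `pulsatility`. `pulsatility = 1` degenerates to constant flow.
#'
#' @param Q_mean mean volumetric flow (m^3/s per unit depth).
#' @param period cardiac period (s).
#' @param systolic_fraction fraction of the period occupied by systole.
#' @param pulsatility peak-to-mean flow ratio; must satisfy
#'   `1 <= pulsatility <= pi / (2 * systolic_fraction)` so the diastolic
#'   baseline stays non-negative.
#' @return an object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(Q_mean, period = 1.0,
                           systolic_fraction = 0.35, pulsatility = 3.0) {
  stopifnot(period > 0, Q_mean >= 0)
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("systolic_fraction must lie in (0, 1)")
  }
  if (pulsatility < 1) stop("pulsatility must be >= 1 (peak-to-mean ratio)")
  k <- 2 * systolic_fraction / pi   # mean of the half-sine over the cycle
  Q_peak <- pulsatility * Q_mean
  Q_dia <- (Q_mean - Q_peak * k) / (1 - k)
  if (Q_dia < -1e-12 * Q_mean) {
    stop(sprintf(
      "pulsatility %.3g too large for systolic_fraction %.3g (flow would reverse); max %.3g",
      pulsatility, systolic_fraction, pi / (2 * systolic_fraction)
    ))
  }
  structure(
    list(
      Q_mean = Q_mean, period = period,
      systolic_fraction = systolic_fraction, pulsatility = pulsatility,
      Q_peak = Q_peak, Q_dia = max(Q_dia, 0)
    ),
    class = "inlet_waveform"
  )
}

#' Evaluate the inlet flow at time t
#'
#' Total, periodic, continuous and non-negative. Vectorized over `t`.
#'
#' @param w an [inlet_waveform()].
#' @param t time(s) in seconds.
#' @return volumetric flow (m^3/s per unit depth).
#' @export
evaluate_inlet_flow <- function(w, t) {
  stopifnot(inherits(w, "inlet_waveform"), all(is.finite(t)))
  tau <- t %% w$period
  ts <- w$systolic_fraction * w$period
  sys <- tau < ts
  q <- rep(w$Q_dia, length(tau))
  q[sys] <- w$Q_dia + (w$Q_peak - w$Q_dia) * sin(pi * tau[sys] / ts)
  q
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf(
    "Inlet waveform: Q_mean %.3g m^3/s, period %.3g s, systole %.0f%%, peak/mean %.2f\n",
    x$Q_mean, x$period, 100 * x$systolic_fraction, x$pulsatility
  ))
  invisible(x)
}
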