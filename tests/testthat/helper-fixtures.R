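# shared fixtures: small geometries and synthetic flow cycles built in code

small_fistula_spec <- function(occlusion_mode = "untreated", ...) {
  geometry_spec(
    D_E = 8, L_F = 30, D_MA = 12, L_A = 8,
    D_aorta = 10, L_aorta = 40, cell_size = 1,
    occlusion_mode = occlusion_mode, ...
  )
}

# synthetic plug-flow cycle: uniform axial velocity U in a channel grid,
# bypassing the momentum solver (verification input for the washout module)
make_plug_cycle <- function(grid, U, nsnap = 100, period = 1.0) {
  u <- matrix(U, grid$nx + 1, grid$ny)
  v <- matrix(0, grid$nx, grid$ny + 1)
  hm <- grid$h * 1e-3
  Q <- U * grid$ny * hm
  snap <- list(u = u, v = v, p = matrix(0, grid$nx, grid$ny),
               t = NA_real_, Q_in = Q,
               Q_out = c(aortic_outlet = Q), P_out = c(aortic_outlet = 0))
  snaps <- lapply(seq_len(nsnap), function(k) {
    snap$t <- k * period / nsnap
    snap
  })
  structure(
    list(snapshots = snaps, period = period, dt = period / nsnap,
         grid_dims = c(grid$nx, grid$ny)),
    class = "flow_cycle"
  )
}

# synthetic wall shear series from a function of time, one face
make_shear_series <- function(f, n = 400, period = 1.0) {
  t <- (seq_len(n) - 0.5) * period / n
  structure(
    list(tau = matrix(f(t), nrow = 1), times = t,
         face_info = data.frame(x = 0, y = 0, region = "fistula",
                                measure = 1),
         period = period),
    class = "wall_shear_series"
  )
}

# minimal stasis report for decision-logic tests
make_report <- function(obvf, obv, high_osi_area = 1, high_osi_proportion = 1,
                        variant = "aneurysm_reserved", d_e = 16,
                        fistula_measure = NULL, aneurysm_measure = 0,
                        config_hash = "h") {
  if (is.null(fistula_measure)) fistula_measure <- if (obvf > 0) 100 * obv / obvf else 1
  structure(
    list(variant = variant, d_e = d_e,
         fistula_measure = fistula_measure,
         aneurysm_measure = aneurysm_measure,
         obvf = obvf, obv = obv,
         high_osi_area = high_osi_area,
         high_osi_proportion = high_osi_proportion,
         low_tawss_area = 0, aortic_flow_pct = NA_real_,
         washout_cycles = 1L, washout_converged = TRUE,
         config_hash = config_hash),
    class = "stasis_report"
  )
}

# brute-force scan of the washout convergence rule, independent of the
# implementation under test
brute_converged <- function(history, window = 10, drop_tol = 1) {
  n <- length(history)
  if (n < window + 1) return(FALSE)
  (history[n - window] - history[n]) < drop_tol
}
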