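# channel verification solves are modest (a few thousand cells) so the whole
# file runs in about a minute

solve_channel <- function(L = 20, H = 4, h = 0.5, U = 0.05, dt = 0.004,
                          pulsatility = 1, period = 1, cycles = 12,
                          snapshots = 50, tol = 1e-6) {
  g <- channel_grid(L, H, h)
  props <- fluid_properties()
  cfg <- solver_config(dt = dt, snapshots_per_cycle = snapshots,
                       n_warmup_cycles = cycles, periodic_tol = tol)
  w <- inlet_waveform(Q_mean = U * H * 1e-3, period = period,
                      pulsatility = pulsatility)
  fl <- simulate_flow(g, props, cfg, w, list(aortic_outlet = outlet_resistor(1e6)))
  list(grid = g, props = props, flow = fl, U = U, H = H)
}

test_that("steady channel flow recovers the fully developed profile and shear", {
  ch <- solve_channel()
  sn <- ch$flow$cycle$snapshots[[50]]
  mid <- round(ch$grid$nx / 2)
  ucc <- 0.5 * (sn$u[mid, ] + sn$u[mid + 1, ])
  # parabolic profile: centerline = 1.5 x mean (8 cells across the channel,
  # cell centers straddle the axis)
  expect_equal(max(ucc) / ch$U, 1.5, tolerance = 0.05)
  # no-slip is exact on wall faces and the wall shear matches 6 mu U / h
  expect_true(all(sn$v[, c(1, ch$grid$ny + 1)] == 0))
  ser <- extract_wall_shear(ch$flow$cycle, ch$grid, ch$props)
  tw <- compute_tawss(ser)
  sel <- ser$face_info$y == 0 & abs(ser$face_info$x - 10) < 5
  tau_exact <- 6 * ch$props$dynamic_viscosity * ch$U / (ch$H * 1e-3)
  expect_equal(mean(tw[sel]), tau_exact, tolerance = 0.05)  # 8 cells across
  # fixed-tangent sign convention: opposite walls carry opposite signs
  top <- ser$face_info$y == ch$H & abs(ser$face_info$x - 10) < 5
  expect_true(all(ser$tau[sel, 50] * ser$tau[top, 50] < 0))
  # global mass conservation at every snapshot
  qin <- vapply(ch$flow$cycle$snapshots, `[[`, numeric(1), "Q_in")
  qout <- vapply(ch$flow$cycle$snapshots, function(s) sum(s$Q_out), numeric(1))
  expect_lt(max(abs(qin - qout) / qin), 0.005)
})

test_that("pulsatile channel shear tracks the quasi-steady value at low Womersley", {
  # Womersley number ~0.8: the cycle is slow against the viscous time
  ch <- solve_channel(L = 10, H = 2.5, h = 2.5 / 12, U = 0.02, dt = 1.25e-3,
                      pulsatility = 2, period = 5, cycles = 3,
                      snapshots = 100, tol = 5e-3)
  ser <- extract_wall_shear(ch$flow$cycle, ch$grid, ch$props)
  sel <- which(ser$face_info$y == 0 & abs(ser$face_info$x - 5) < 2)
  tau_t <- colMeans(ser$tau[sel, , drop = FALSE])
  w <- inlet_waveform(Q_mean = ch$U * ch$H * 1e-3, period = 5, pulsatility = 2)
  Umean_t <- evaluate_inlet_flow(w, ser$times) / (ch$H * 1e-3)
  tau_qs <- 6 * ch$props$dynamic_viscosity * Umean_t / (ch$H * 1e-3)
  expect_lt(max(abs(tau_t - tau_qs) / max(tau_qs)), 0.05)
})

test_that("an occluded fistula stores no net flow over a cycle", {
  spec <- small_fistula_spec("aneurysm_reserved")
  grid <- build_fistula_geometry(spec)
  props <- fluid_properties()
  cfg <- solver_config(dt = 0.01, snapshots_per_cycle = 100,
                       n_warmup_cycles = 4, periodic_tol = 5e-3)
  w <- inlet_waveform(Q_mean = 2e-4)
  fl <- simulate_flow(grid, props, cfg, w,
                      list(aortic_outlet = outlet_rcr(2.3171e8)))
  # net flux through the fistula entrance plane, integrated over the cycle
  jrow <- max(which(grid$yc < spec$L_F))   # last fistula row below the aorta
  cols <- which(!is.na(grid$region[, jrow]) & grid$region[, jrow] == 2L)
  hm <- grid$h * 1e-3
  qf <- vapply(fl$cycle$snapshots, function(s) {
    sum(s$v[cols, jrow + 1]) * hm
  }, numeric(1))
  expect_lt(abs(mean(qf)) / w$Q_mean, 1e-6)
})

test_that("periodic-convergence metric behaves on constructed cycles", {
  ch <- solve_channel(cycles = 2, tol = 1e-12)
  cyc <- ch$flow$cycle
  same <- check_periodic_convergence(cyc, cyc)
  expect_true(same$converged)
  expect_equal(same$metric, 0)
  scaled <- cyc
  scaled$snapshots <- lapply(cyc$snapshots, function(s) {
    s$u <- 1.01 * s$u; s$v <- 1.01 * s$v; s
  })
  chk <- check_periodic_convergence(cyc, scaled, tol = 5e-3)
  expect_false(chk$converged)
  expect_equal(chk$metric, 0.01, tolerance = 2e-2)
  short <- cyc
  short$snapshots <- cyc$snapshots[1:10]
  expect_error(check_periodic_convergence(cyc, short), "mismatched")
})

test_that("zero flow produces zero wall shear everywhere", {
  g <- channel_grid(10, 5, 0.5)
  cyc <- make_plug_cycle(g, U = 0)
  ser <- extract_wall_shear(cyc, g, fluid_properties())
  expect_true(all(ser$tau == 0))
})

test_that("solver configuration contracts are enforced", {
  g <- channel_grid(10, 5, 0.5)
  w <- inlet_waveform(Q_mean = 1e-4)
  expect_error(
    flow_init(g, fluid_properties(), solver_config(dt = 0.3), w,
              list(aortic_outlet = outlet_resistor(1e6))),
    "divide"
  )
  expect_error(
    flow_init(g, fluid_properties(), solver_config(dt = 0.01,
                                                   snapshots_per_cycle = 33),
              w, list(aortic_outlet = outlet_resistor(1e6))),
    "snapshots_per_cycle"
  )
  expect_error(
    flow_init(g, fluid_properties(), solver_config(), w,
              list(coronary_outlet = outlet_resistor(1e6))),
    "missing outlet"
  )
})
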