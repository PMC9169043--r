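test_that("TAWSS matches closed forms and refined quadrature", {
  s <- make_shear_series(function(t) rep(2, length(t)))
  expect_equal(unname(compute_tawss(s)), 2)
  s <- make_shear_series(function(t) sin(2 * pi * t))
  expect_equal(unname(compute_tawss(s)), 2 / pi, tolerance = 5e-3)
  # arbitrary series vs 10x-oversampled quadrature
  f <- function(t) 0.8 + 0.5 * sin(2 * pi * t) + 0.3 * cos(4 * pi * t + 1)
  coarse <- compute_tawss(make_shear_series(f, n = 100))
  fine <- compute_tawss(make_shear_series(f, n = 1000))
  expect_equal(unname(coarse), unname(fine), tolerance = 0.01)
  expect_error(compute_tawss(matrix(numeric(0), nrow = 1)), "empty")
})

test_that("OSI spans [0, 0.5] with the right limits", {
  uni <- make_shear_series(function(t) 1 + 0.5 * sin(2 * pi * t))
  expect_equal(unname(compute_osi(uni)), 0)
  rev <- make_shear_series(function(t) sin(2 * pi * t))
  expect_equal(unname(compute_osi(rev)), 0.5, tolerance = 1e-9)
  zero <- make_shear_series(function(t) rep(0, length(t)))
  expect_equal(unname(compute_osi(zero)), 0)   # degenerate convention
  # partially reversing: check against the defining quadrature
  f <- function(t) 0.5 + sin(2 * pi * t)
  t <- (seq_len(1e5) - 0.5) / 1e5
  osi_quad <- 0.5 * (1 - abs(mean(f(t))) / mean(abs(f(t))))
  expect_equal(unname(compute_osi(make_shear_series(f, n = 1000))), osi_quad,
               tolerance = 1e-3)
  # hard bound on arbitrary series
  set.seed(42)
  for (k in 1:20) {
    tau <- matrix(rnorm(200), nrow = 2)
    osi <- compute_osi(tau)
    expect_true(all(osi >= 0 & osi <= 0.5))
  }
})

test_that("TAWSS and OSI are invariant to the tangent sign convention", {
  set.seed(7)
  tau <- matrix(rnorm(300) + 0.3, nrow = 3)
  expect_equal(compute_tawss(-tau), compute_tawss(tau))
  expect_equal(compute_osi(-tau), compute_osi(tau))
})

test_that("threshold_area reproduces constructed half/half fields exactly", {
  map <- structure(
    data.frame(
      x = 1:10, y = 0,
      region = rep(c("fistula", "aorta"), each = 5),
      measure = 2,
      tawss = 1, tawss_dyne = 10,
      osi = c(0.45, 0.45, 0.05, 0.05, 0.45, rep(0.4, 5))
    ),
    class = c("wall_metric_map", "data.frame")
  )
  # fistula scope: 3 of 5 faces above 0.3
  r <- threshold_area(map, "osi", 0.3, ">", "fistula_wall")
  expect_equal(r$area, 6)
  expect_equal(r$proportion, 60)
  all100 <- threshold_area(map, "osi", 0.3, ">", "all_wall")
  expect_equal(all100$proportion, 80)
  none <- threshold_area(map, "osi", 0.5, ">", "fistula_wall")
  expect_equal(none$area, 0)
  expect_equal(none$proportion, 0)
  expect_error(threshold_area(map, "osi", 0.3, ">", "lumen"), "scope")
})

test_that("OBV is the OBVF share of the fistula volume", {
  expect_equal(compute_obv(100, 20262), 20262)
  expect_equal(compute_obv(0, 20262), 0)
  # magnitude anchor: 16.4% of a 20262 mm^3 fistula is about 3323 mm^3
  expect_equal(compute_obv(16.4, 20262), 3322.968)
  expect_error(compute_obv(120, 100), "OBVF")
  expect_error(compute_obv(50, 0), "positive")
})

test_that("flow split normalizes cycle-averaged outlet fluxes", {
  g <- channel_grid(16, 4, 0.5)
  cyc <- make_plug_cycle(g, U = 0.02)
  sp <- compute_flow_split(cyc, g)
  expect_equal(unname(sp[["aortic_outlet"]]), 100)
  # synthetic two-outlet cycle: 70/30 split with a 1% conservation warning
  cyc2 <- cyc
  cyc2$snapshots <- lapply(cyc$snapshots, function(s) {
    q <- s$Q_in
    s$Q_out <- c(aortic_outlet = 0.68 * q, fistula_outlet = 0.3 * q)
    s
  })
  sp2 <- compute_flow_split(cyc2, g)
  expect_equal(as.numeric(sp2), c(68, 30))
  expect_gt(attr(sp2, "conservation_error"), 1)
  expect_match(attr(sp2, "warning"), "conserve")
})
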