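test_that("geometry spec validation enforces the morphological invariants", {
  expect_error(geometry_spec(D_E = 10, L_F = 50, D_MA = 8), "D_MA")
  expect_error(geometry_spec(D_E = 10, L_F = 5, D_MA = 12, L_A = 8), "L_F")
  expect_error(geometry_spec(D_E = -1, L_F = 50), "D_E")
  expect_error(geometry_spec(D_E = 10, L_F = 50, cell_size = 2),
               "resolution floor")
  # the resolution-floor error names the limiting dimension
  expect_error(geometry_spec(D_E = 10, L_F = 50, cell_size = 2), "D_E")
})

test_that("printed-table morphology parameters build a grid with an aneurysm", {
  spec <- geometry_spec(D_E = 16.3, L_F = 130.2, D_MA = 40.8, L_A = 39,
                        cell_size = 2)
  grid <- build_fistula_geometry(spec)
  expect_gt(region_measure(grid, "aneurysm"), 0)
  expect_gt(region_measure(grid, "fistula"), region_measure(grid, "aneurysm"))
})

test_that("occlusion variants relabel only the terminal segment", {
  specs <- lapply(c("untreated", "aneurysm_reserved", "aneurysm_removed"),
                  function(m) small_fistula_spec(m, D_branch = 3))
  grids <- lapply(specs, build_fistula_geometry)
  names(grids) <- c("untreated", "reserved", "removed")

  # untreated exposes a fistula outlet, occluded variants do not
  n_fout <- vapply(grids, function(g) {
    sum(g$v_type == caflow:::FACE_FISTULA_OUTLET)
  }, numeric(1))
  expect_gt(n_fout[["untreated"]], 0)
  expect_identical(unname(n_fout[c("reserved", "removed")]), c(0, 0))

  # removed variant has no aneurysm cells and strictly less fistula measure
  expect_identical(region_measure(grids$removed, "aneurysm"), 0)
  expect_lt(region_measure(grids$removed, "fistula"),
            region_measure(grids$reserved, "fistula"))

  # cell-by-cell equality in the parent-vessel region across variants
  aorta_rows <- which(grids$untreated$yc >= specs[[1]]$L_F)
  for (g in grids[-1]) {
    expect_identical(g$fluid[, aorta_rows], grids$untreated$fluid[, aorta_rows])
    expect_identical(g$region[, aorta_rows], grids$untreated$region[, aorta_rows])
  }
})

test_that("rasterized region measures converge to the analytic areas", {
  # straight 10 x 100 channel: exact rectangle area at aligned spacing
  for (h in c(1, 0.5)) {
    spec <- geometry_spec(D_E = 10, L_F = 100, D_MA = 10, L_A = 0,
                          cell_size = h)
    grid <- build_fistula_geometry(spec)
    expect_equal(region_measure(grid, "fistula"), 1000,
                 tolerance = 0.02)
  }
  # rectangle-composed fistula+aneurysm: 2x refinement moves measures < 2%
  m <- lapply(c(1, 0.5), function(h) {
    g <- build_fistula_geometry(
      geometry_spec(D_E = 9, L_F = 33, D_MA = 21, L_A = 11,
                    D_aorta = 13, L_aorta = 41, cell_size = h)
    )
    c(region_measure(g, "aorta"), region_measure(g, "fistula"),
      region_measure(g, "aneurysm"))
  })
  expect_true(all(abs(m[[2]] / m[[1]] - 1) < 0.02))
})

test_that("boundary labels partition the fluid boundary", {
  grid <- build_fistula_geometry(small_fistula_spec("untreated", D_branch = 3))
  pad <- rbind(FALSE, grid$fluid, FALSE)
  u_fluid_sides <- pad[1:(grid$nx + 1), ] + pad[2:(grid$nx + 2), ]
  # one fluid neighbour -> exactly one non-interior label; two -> interior
  expect_true(all(grid$u_type[u_fluid_sides == 2] == caflow:::FACE_INTERIOR))
  expect_true(all(grid$u_type[u_fluid_sides == 1] != caflow:::FACE_INTERIOR))
  expect_true(all(grid$u_type[u_fluid_sides == 1] != caflow:::FACE_INACTIVE))
  expect_true(all(grid$u_type[u_fluid_sides == 0] == caflow:::FACE_INACTIVE))
  pad2 <- cbind(FALSE, grid$fluid, FALSE)
  v_fluid_sides <- pad2[, 1:(grid$ny + 1)] + pad2[, 2:(grid$ny + 2)]
  expect_true(all(grid$v_type[v_fluid_sides == 1] != caflow:::FACE_INTERIOR))
  expect_true(all(grid$v_type[v_fluid_sides == 1] != caflow:::FACE_INACTIVE))
  expect_true(all(grid$v_type[v_fluid_sides == 0] == caflow:::FACE_INACTIVE))
  # every fluid cell carries exactly one region tag
  expect_false(any(is.na(grid$region[grid$fluid])))
  expect_true(all(is.na(grid$region[!grid$fluid])))
})

test_that("region_measure sums tagged cells and rejects unknown tags", {
  g <- channel_grid(10, 10, 1, region = "aorta")
  expect_equal(region_measure(g, "aorta"), 100)
  expect_error(region_measure(g, "ventricle"), "unknown region")
})
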