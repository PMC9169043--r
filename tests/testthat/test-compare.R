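test_that("treatment comparison computes the derived fields", {
  cmp <- compare_treatments(
    make_report(50, 1000, high_osi_area = 2, high_osi_proportion = 2),
    make_report(20, 400, high_osi_area = 1, high_osi_proportion = 1),
    volumes = list(V_A = 300, V_F = 1000)
  )
  expect_equal(cmp$obv_rel_diff, 60)
  expect_equal(cmp$va_vf_ratio, 0.3)
  expect_true(cmp$all_metrics_decreased)

  # identical reports: zero difference, nothing strictly decreased
  same <- compare_treatments(make_report(50, 1000), make_report(50, 1000))
  expect_equal(same$obv_rel_diff, 0)
  expect_false(same$all_metrics_decreased)
  expect_setequal(same$non_decreasing_metrics,
                  c("high_osi_proportion", "high_osi_area", "obvf", "obv"))

  expect_error(
    compare_treatments(make_report(50, 1000, config_hash = "a"),
                       make_report(20, 400, config_hash = "b")),
    "mismatched"
  )
})

test_that("occlusion recommendation reproduces the narrative decision rules", {
  # large OBV difference: proximal occlusion selected directly
  cmp <- compare_treatments(make_report(50, 1000), make_report(10, 300),
                            volumes = list(V_A = 100, V_F = 1000))
  expect_equal(recommend_occlusion(cmp)$choice, "proximal")
  expect_true("obv_difference_large" %in% recommend_occlusion(cmp)$rationale)

  # sub-threshold difference with a small aneurysm: either treatment
  small_an <- compare_treatments(make_report(50, 1000), make_report(35, 600),
                                 volumes = list(V_A = 923, V_F = 33230))
  expect_equal(recommend_occlusion(small_an)$choice, "either")

  # sub-threshold difference with a dominant aneurysm: distal occlusion
  big_an <- compare_treatments(make_report(50, 1000), make_report(35, 600),
                               volumes = list(V_A = 7055, V_F = 20262))
  expect_equal(recommend_occlusion(big_an)$choice, "distal")

  # degenerate comparison
  degen <- compare_treatments(make_report(0, 0), make_report(0, 0))
  rec <- recommend_occlusion(degen)
  expect_equal(rec$choice, "either")
  expect_true("degenerate_obv_reserved_zero" %in% rec$rationale)
})

test_that("the recommendation is monotone in the OBV difference", {
  choices <- vapply(seq(0, 95, by = 5), function(d) {
    cmp <- compare_treatments(make_report(50, 1000),
                              make_report(50 * (1 - d / 100), 1000 * (1 - d / 100)),
                              volumes = list(V_A = 100, V_F = 1000))
    recommend_occlusion(cmp)$choice
  }, character(1))
  # once proximal, always proximal as the difference grows
  first_prox <- match("proximal", choices)
  expect_true(all(choices[first_prox:length(choices)] == "proximal"))
  expect_true(all(choices[seq_len(first_prox - 1)] != "proximal"))

  # degenerate threshold 0: any positive difference selects proximal
  cmp <- compare_treatments(make_report(50, 1000), make_report(49, 990))
  expect_equal(recommend_occlusion(cmp, obv_diff_threshold = 0)$choice,
               "proximal")
})

test_that("the anticoagulation flag follows the 8 mm entrance-diameter rule", {
  cmp_big <- compare_treatments(make_report(50, 1000, d_e = 16),
                                make_report(20, 400, d_e = 16))
  expect_true(recommend_occlusion(cmp_big)$anticoagulation_indicated)
  cmp_small <- compare_treatments(make_report(50, 1000, d_e = 6),
                                  make_report(20, 400, d_e = 6))
  expect_false(recommend_occlusion(cmp_small)$anticoagulation_indicated)
})
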