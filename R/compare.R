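# Occlusion-position decision logic: compare the four thrombosis metrics
# between the aneurysm-reserved (distal occlusion) and aneurysm-removed
# (proximal occlusion) variants and recommend an occlusion position from the
# relative OBV difference with a morphological tie-break.

#' Compare the two occlusion treatments
#'
#' Populates the derived comparison fields: the relative OBV difference
#' `100 * (OBV_reserved - OBV_removed) / OBV_reserved` and the
#' aneurysm-to-fistula volume ratio `V_A / V_F` of the reserved (intact)
#' anatomy, and flags any of the four metrics that did not decrease in the
#' removed variant.
#'
#' @param reserved,removed `stasis_report`s of the aneurysm-reserved and
#'   aneurysm-removed variants from matched configurations.
#' @param volumes optional list with `V_A`, `V_F` (mm^3); defaults to the
#'   measures recorded in the reserved report.
#' @return object of class `treatment_comparison`.
#' @export
compare_treatments <- function(reserved, removed, volumes = NULL) {
  stopifnot(inherits(reserved, "stasis_report"), inherits(removed, "stasis_report"))
  if (!is.na(reserved$config_hash) && !is.na(removed$config_hash) &&
      reserved$config_hash != removed$config_hash) {
    stop("reports come from mismatched configurations")
  }
  V_A <- if (!is.null(volumes)) volumes$V_A else reserved$aneurysm_measure
  V_F <- if (!is.null(volumes)) volumes$V_F else reserved$fistula_measure
  if (V_F <= 0) stop("fistula volume must be positive")
  rel_diff <- if (reserved$obv > 0) {
    100 * (reserved$obv - removed$obv) / reserved$obv
  } else NA_real_
  metrics <- c("high_osi_proportion", "high_osi_area", "obvf", "obv")
  decreased <- vapply(metrics, function(m) {
    removed[[m]] < reserved[[m]]
  }, logical(1))
  structure(
    list(
      reserved = reserved, removed = removed,
      obv_rel_diff = rel_diff,
      va_vf_ratio = V_A / V_F,
      all_metrics_decreased = all(decreased),
      non_decreasing_metrics = metrics[!decreased]
    ),
    class = "treatment_comparison"
  )
}

#' Recommend an occlusion position
#'
#' Decision rule: a large relative OBV difference (at or above
#' `obv_diff_threshold`) means proximal occlusion clearly reduces stasis and
#' is selected directly. Below the threshold, morphology decides: a small
#' aneurysm relative to the fistula (`V_A/V_F` below
#' `aneurysm_dominance_threshold`) makes either treatment acceptable, while
#' a dominant aneurysm - whose removal would sacrifice the supply fed
#' through the terminal segment - favours distal occlusion. A degenerate
#' comparison (`OBV_reserved = 0`) yields `"either"`.
#'
#' @param cmp a `treatment_comparison`.
#' @param obv_diff_threshold relative OBV difference (%) above which
#'   proximal occlusion is selected directly.
#' @param aneurysm_dominance_threshold `V_A/V_F` ratio above which the
#'   aneurysm counts as dominant.
#' @return object of class `occlusion_recommendation` with `choice`
#'   (`"proximal"`, `"distal"` or `"either"`), `rationale` tokens naming the
#'   fired rule, and `anticoagulation_indicated` (fistula entrance diameter
#'   above 8 mm, when the geometry is known).
#' @export
recommend_occlusion <- function(cmp, obv_diff_threshold = 50,
                                aneurysm_dominance_threshold = 0.25) {
  stopifnot(inherits(cmp, "treatment_comparison"))
  d <- cmp$obv_rel_diff
  if (is.na(d)) {
    choice <- "either"
    rationale <- c("degenerate_obv_reserved_zero")
  } else if (d >= obv_diff_threshold) {
    choice <- "proximal"
    rationale <- c("obv_difference_large")
  } else if (cmp$va_vf_ratio < aneurysm_dominance_threshold) {
    choice <- "either"
    rationale <- c("obv_difference_small", "aneurysm_small")
  } else {
    choice <- "distal"
    rationale <- c("obv_difference_small", "aneurysm_dominant")
  }
  d_e <- cmp$reserved$d_e
  structure(
    list(
      choice = choice, rationale = rationale,
      obv_rel_diff = d, va_vf_ratio = cmp$va_vf_ratio,
      obv_diff_threshold = obv_diff_threshold,
      aneurysm_dominance_threshold = aneurysm_dominance_threshold,
      anticoagulation_indicated = if (is.null(d_e)) NA else d_e > 8
    ),
    class = "occlusion_recommendation"
  )
}

#' @export
print.occlusion_recommendation <- function(x, ...) {
  cat(sprintf("Occlusion recommendation: %s\n", x$choice))
  cat(sprintf("  OBV relative difference %.1f %% (threshold %.0f %%)\n",
              x$obv_rel_diff, x$obv_diff_threshold))
  cat(sprintf("  V_A/V_F %.3f (dominance threshold %.2f)\n",
              x$va_vf_ratio, x$aneurysm_dominance_threshold))
  cat(sprintf("  rule: %s\n", paste(x$rationale, collapse = " + ")))
  invisible(x)
}
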