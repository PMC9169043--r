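# Wall-shear-derived thrombosis metrics (TAWSS, OSI, thresholded areas) and
# the stasis metrics (OBVF, OBV), plus the outlet flow-split diagnostic.
# Threshold conventions follow common arterial practice: high OSI > 0.3 and
# low TAWSS < 10 dyne/cm^2 (= 1 Pa) mark thrombosis-prone wall.

# periodic trapezoid: mean of f over one period from uniform samples,
# closing the cycle by wrapping the first sample
.periodic_mean <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty series")
  mean(x)  # uniform periodic samples: trapezoid with wrap == arithmetic mean
}

#' Time-averaged wall shear stress
#'
#' `TAWSS = (1/T) integral |tau| dt` over one periodic cycle, evaluated with
#' the trapezoid rule on the uniformly spaced periodic samples.
#'
#' @param series a `wall_shear_series` (or a numeric vector / matrix of
#'   samples, faces in rows).
#' @return per-face TAWSS (Pa). Multiply by 10 for dyne/cm^2.
#' @export
compute_tawss <- function(series) {
  tau <- if (inherits(series, "wall_shear_series")) series$tau else series
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  if (ncol(tau) == 0) stop("empty wall shear series")
  apply(abs(tau), 1, .periodic_mean)
}

#' Oscillatory shear index
#'
#' `OSI = 0.5 * (1 - |integral tau dt| / integral |tau| dt)`, in `[0, 0.5]`:
#' 0 for unidirectional shear, 0.5 for zero-mean fully reversing shear.
#' A degenerate all-zero series yields 0 by convention.
#'
#' @inheritParams compute_tawss
#' @return per-face OSI (dimensionless).
#' @export
compute_osi <- function(series) {
  tau <- if (inherits(series, "wall_shear_series")) series$tau else series
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = 1)
  m_abs <- apply(abs(tau), 1, .periodic_mean)
  m_sgn <- abs(apply(tau, 1, .periodic_mean))
  osi <- ifelse(m_abs > 0, 0.5 * (1 - m_sgn / m_abs), 0)
  pmin(pmax(osi, 0), 0.5)
}

#' Wall metric map
#'
#' Bundles per-face TAWSS and OSI with the face measures and regions needed
#' for thresholded-area queries.
#'
#' @param series a `wall_shear_series`.
#' @return object of class `wall_metric_map` with columns `tawss` (Pa),
#'   `tawss_dyne` (dyne/cm^2), `osi`, `measure` (mm^2), `region`.
#' @export
wall_metric_map <- function(series) {
  stopifnot(inherits(series, "wall_shear_series"))
  df <- series$face_info
  df$tawss <- compute_tawss(series)
  df$tawss_dyne <- 10 * df$tawss
  df$osi <- compute_osi(series)
  structure(df, class = c("wall_metric_map", "data.frame"))
}

#' Thresholded wall area and proportion
#'
#' Area (face measures summed, mm^2 with the unit-depth convention) of the
#' wall where a metric passes a threshold, and that area as a percentage of
#' the scope's total wall area. The default scope is the fistula wall
#' (fistula plus aneurysm regions), the region whose thrombosis the stasis
#' analysis quantifies; `"all_wall"` uses every wall face.
#'
#' @param map a `wall_metric_map`.
#' @param metric column to threshold (`"osi"`, `"tawss"`, `"tawss_dyne"`).
#' @param threshold threshold value.
#' @param direction `">"` (high passes) or `"<"` (low passes).
#' @param region_scope `"fistula_wall"` or `"all_wall"`.
#' @return list with `area` (mm^2) and `proportion` (%).
#' @export
threshold_area <- function(map, metric = "osi", threshold = 0.3,
                           direction = ">", region_scope = "fistula_wall") {
  stopifnot(inherits(map, "wall_metric_map"), nrow(map) > 0)
  if (!metric %in% names(map)) stop(sprintf("unknown metric '%s'", metric))
  direction <- match.arg(direction, c(">", "<"))
  scope <- switch(region_scope,
    fistula_wall = map$region %in% c("fistula", "aneurysm"),
    all_wall = rep(TRUE, nrow(map)),
    stop(sprintf("unknown region scope '%s'", region_scope))
  )
  total <- sum(map$measure[scope])
  if (total == 0) return(list(area = 0, proportion = 0))
  vals <- map[[metric]][scope]
  pass <- if (direction == ">") vals > threshold else vals < threshold
  area <- sum(map$measure[scope][pass])
  list(area = area, proportion = 100 * area / total)
}

#' Old blood volume
#'
#' `OBV = OBVF/100 * fistula measure`, the volumetric stasis metric.
#'
#' @param obvf old blood volume fraction (percent, in `[0, 100]`).
#' @param fistula_measure fistula measure (mm^3 equivalent).
#' @return OBV (mm^3 equivalent).
#' @export
compute_obv <- function(obvf, fistula_measure) {
  if (!is.finite(obvf) || obvf < 0 || obvf > 100) {
    stop(sprintf("OBVF must lie in [0, 100] percent (got %.3g)", obvf))
  }
  if (fistula_measure <= 0) stop("fistula measure must be positive")
  obvf / 100 * fistula_measure
}

#' Cycle-averaged outlet flow split
#'
#' Cycle-integrated flux through each outlet label of the periodic cycle,
#' normalized by the cycle-integrated inlet flux, as percentages. A
#' conservation mismatch above 1% attaches a warning to the result.
#'
#' @param cycle a `flow_cycle` (snapshots must carry `Q_in`/`Q_out`, as
#'   produced by [advance_cycle()]).
#' @param grid the `domain_grid` (retained for interface symmetry; fluxes
#'   are stored on the snapshots).
#' @return named numeric of per-outlet percentages, with attribute
#'   `conservation_error` (percent of inlet flux); a `warning` attribute is
#'   attached when the mismatch exceeds 1%.
#' @export
compute_flow_split <- function(cycle, grid = NULL) {
  stopifnot(inherits(cycle, "flow_cycle"))
  qin <- vapply(cycle$snapshots, `[[`, numeric(1), "Q_in")
  n_out <- length(cycle$snapshots[[1]]$Q_out)
  qout <- matrix(
    vapply(cycle$snapshots, `[[`, numeric(n_out), "Q_out"),
    nrow = n_out
  )
  mean_in <- mean(qin)
  mean_out <- rowMeans(qout)
  pct <- 100 * mean_out / mean_in
  names(pct) <- names(cycle$snapshots[[1]]$Q_out)
  cons <- 100 * abs(mean_in - sum(mean_out)) / mean_in
  attr(pct, "conservation_error") <- cons
  if (cons > 1) {
    attr(pct, "warning") <- sprintf(
      "outlet fluxes conserve inlet flux only to %.2f%%", cons)
  }
  pct
}

#' Per-variant stasis report
#'
#' Collects the four thrombosis metrics (proportion and area of high OSI,
#' OBVF, OBV) plus the TAWSS and flow-split diagnostics for one occlusion
#' variant.
#'
#' @param variant occlusion mode of the variant.
#' @param grid the variant's `domain_grid`.
#' @param map a `wall_metric_map` for the variant.
#' @param washout a `washout_result`.
#' @param flow_split result of [compute_flow_split()].
#' @param osi_threshold,tawss_threshold_dyne thresholds for the high-OSI and
#'   low-TAWSS areas.
#' @param config_hash identifier tying reports of matched configurations.
#' @return object of class `stasis_report`.
#' @export
stasis_report <- function(variant, grid, map, washout, flow_split,
                          osi_threshold = 0.3, tawss_threshold_dyne = 10,
                          config_hash = NA_character_) {
  fist <- region_measure(grid, "fistula")
  obvf <- as.numeric(utils::tail(unclass(washout$history), 1))
  high_osi <- threshold_area(map, "osi", osi_threshold, ">")
  low_tawss <- threshold_area(map, "tawss_dyne", tawss_threshold_dyne, "<")
  aortic <- if ("aortic_outlet" %in% names(flow_split)) {
    as.numeric(flow_split[["aortic_outlet"]])
  } else NA_real_
  structure(
    list(
      variant = variant,
      d_e = grid$spec$D_E,
      fistula_measure = fist,
      aneurysm_measure = region_measure(grid, "aneurysm"),
      obvf = obvf,
      obv = compute_obv(obvf, fist),
      high_osi_area = high_osi$area,
      high_osi_proportion = high_osi$proportion,
      low_tawss_area = low_tawss$area,
      aortic_flow_pct = aortic,
      washout_cycles = washout$cycles,
      washout_converged = washout$converged,
      config_hash = config_hash
    ),
    class = "stasis_report"
  )
}

#' @export
print.stasis_report <- function(x, ...) {
  cat(sprintf("Stasis report (%s):\n", x$variant))
  cat(sprintf("  OBVF %.2f %%   OBV %.1f mm^3 (fistula %.0f mm^3)\n",
              x$obvf, x$obv, x$fistula_measure))
  cat(sprintf("  high-OSI: %.1f %% of fistula wall, area %.1f mm^2\n",
              x$high_osi_proportion, x$high_osi_area))
  cat(sprintf("  low-TAWSS area %.1f mm^2   aortic flow %.2f %%\n",
              x$low_tawss_area, x$aortic_flow_pct))
  invisible(x)
}
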