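# File-format I/O: VTK legacy structured-points snapshots (cell data),
# CSV time series/histories, JSON reports and configs.

.vtk_header <- function(con, grid, title) {
  writeLines(c(
    "# vtk DataFile Version 3.0",
    title,
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", grid$nx + 1, grid$ny + 1, 2),
    "ORIGIN 0 0 0",
    sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
    sprintf("CELL_DATA %d", grid$nx * grid$ny)
  ), con)
}

.vtk_scalar <- function(con, name, values) {
  writeLines(c(
    sprintf("SCALARS %s float 1", name),
    "LOOKUP_TABLE default"
  ), con)
  writeLines(paste(format(values, scientific = TRUE, digits = 9,
                          trim = TRUE), collapse = " "), con)
}

#' Write a domain grid as a VTK legacy structured-points file
#'
#' Cell data: `label` (1 fluid, 0 solid) and `region` (0 solid, 1 aorta,
#' 2 fistula, 3 aneurysm). A JSON sidecar `<path>.json` records the
#' originating geometry spec.
#'
#' @param grid a `domain_grid`.
#' @param path output path (`.vtk`).
#' @export
write_grid_vtk <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, grid, sprintf("caflow domain grid (%s)",
                                 grid$spec$occlusion_mode))
  .vtk_scalar(con, "label", as.numeric(grid$fluid))
  region <- grid$region
  region[is.na(region)] <- 0L
  .vtk_scalar(con, "region", as.numeric(region))
  jsonlite::write_json(
    unclass(grid$spec), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a flow snapshot as a VTK legacy file
#'
#' Cell data: cell-centered `u`, `v` (m/s) and `p` (Pa).
#'
#' @param snap one snapshot from a `flow_cycle`.
#' @param grid the `domain_grid`.
#' @param path output path.
#' @export
write_snapshot_vtk <- function(snap, grid, path) {
  nx <- grid$nx; ny <- grid$ny
  ucc <- 0.5 * (snap$u[-(nx + 1), , drop = FALSE] + snap$u[-1, , drop = FALSE])
  vcc <- 0.5 * (snap$v[, -(ny + 1), drop = FALSE] + snap$v[, -1, drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, grid, sprintf("caflow flow snapshot t=%g", snap$t))
  .vtk_scalar(con, "u", as.numeric(ucc))
  .vtk_scalar(con, "v", as.numeric(vcc))
  .vtk_scalar(con, "p", as.numeric(snap$p))
  invisible(path)
}

#' Write an old-blood fraction field as a VTK legacy file
#'
#' Cell data: `alpha` (old-blood fraction; solid cells carry -1).
#'
#' @param field a `fraction_field`.
#' @param grid the `domain_grid`.
#' @param path output path.
#' @export
write_fraction_vtk <- function(field, grid, path) {
  a <- field$alpha
  a[is.na(a)] <- -1
  con <- file(path, "w")
  on.exit(close(con))
  .vtk_header(con, grid, sprintf("caflow old-blood fraction t=%g", field$t))
  .vtk_scalar(con, "alpha", as.numeric(a))
  invisible(path)
}

#' Read cell-data scalars back from a VTK legacy file written by this package
#'
#' @param path path to a `.vtk` file produced by the writers above.
#' @return named list of numeric vectors (one per SCALARS block) plus
#'   attributes `dims` (cells) and `spacing`.
#' @export
read_vtk_cell_data <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(sub("DIMENSIONS", "",
                                         grep("^DIMENSIONS", lines, value = TRUE))),
                              "\\s+")[[1]])
  spacing <- as.numeric(strsplit(trimws(sub("SPACING", "",
                                            grep("^SPACING", lines, value = TRUE))),
                                 "\\s+")[[1]])
  ncell <- prod(dims - 1)
  out <- list()
  idx <- grep("^SCALARS", lines)
  for (k in idx) {
    name <- strsplit(lines[k], "\\s+")[[1]][2]
    vals <- as.numeric(strsplit(trimws(lines[k + 2]), "\\s+")[[1]])
    if (length(vals) != ncell) {
      stop(sprintf("scalar '%s' has %d values, expected %d cells",
                   name, length(vals), ncell))
    }
    out[[name]] <- vals
  }
  attr(out, "dims") <- dims - 1L
  attr(out, "spacing") <- spacing
  out
}

#' Write a washout history as CSV (cycle index, OBVF percent)
#'
#' @param history a `washout_history` (numeric, cycle 0 first).
#' @param path output path.
#' @export
write_history_csv <- function(history, path) {
  df <- data.frame(cycle = seq_along(history) - 1L,
                   OBVF_percent = as.numeric(history))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a wall shear series as long-format CSV
#'
#' One row per (face, time): face id, position (mm), region, time (s) and
#' the signed shear sample (Pa).
#'
#' @param series a `wall_shear_series`.
#' @param path output path.
#' @export
write_wall_shear_csv <- function(series, path) {
  stopifnot(inherits(series, "wall_shear_series"))
  nf <- nrow(series$tau); nt <- ncol(series$tau)
  df <- data.frame(
    face = rep(seq_len(nf), times = nt),
    x = rep(series$face_info$x, times = nt),
    y = rep(series$face_info$y, times = nt),
    t = rep(series$times, each = nf),
    tau = as.vector(series$tau)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a stasis report as a one-row CSV
#'
#' @param x a `stasis_report`.
#' @param path output path.
#' @export
write_report_csv <- function(x, path) {
  stopifnot(inherits(x, "stasis_report"))
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE)
  invisible(path)
}

#' Write a wall metric map as CSV
#'
#' @param map a `wall_metric_map`.
#' @param path output path.
#' @export
write_wall_metrics_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Write a stasis report (or comparison/recommendation) as JSON
#'
#' @param x a `stasis_report`, `treatment_comparison` or
#'   `occlusion_recommendation`.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(.report_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.report_to_list <- function(x) {
  if (inherits(x, "treatment_comparison")) {
    list(
      reserved = .report_to_list(x$reserved),
      removed = .report_to_list(x$removed),
      obv_rel_diff = x$obv_rel_diff,
      va_vf_ratio = x$va_vf_ratio,
      all_metrics_decreased = x$all_metrics_decreased,
      non_decreasing_metrics = as.list(x$non_decreasing_metrics)
    )
  } else {
    lapply(unclass(x), function(el) if (is.null(el)) NA else el)
  }
}

#' Read a stasis report back from JSON
#'
#' @param path path written by [write_report_json()].
#' @return a `stasis_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "stasis_report")
}
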