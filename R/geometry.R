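# Synthetic fistula-with-terminal-aneurysm geometry on a labelled Cartesian
# grid. All lengths in mm; the 2D plane carries a unit (1 mm) out-of-plane
# depth, so "volumes" are areas x 1 mm and carry mm^3-equivalent units.

# face type codes (u faces: vertical faces, normal +x; v faces: horizontal)
FACE_INACTIVE <- 0L  # both neighbours solid / outside
FACE_INTERIOR <- 1L  # fluid-fluid
FACE_WALL <- 2L
FACE_INLET <- 3L
FACE_AORTIC_OUTLET <- 4L
FACE_CORONARY_OUTLET <- 5L
FACE_FISTULA_OUTLET <- 6L

REGION_LEVELS <- c("aorta", "fistula", "aneurysm")
OUTLET_FACE_CODES <- c(FACE_AORTIC_OUTLET, FACE_CORONARY_OUTLET, FACE_FISTULA_OUTLET)
OCCLUSION_MODES <- c("untreated", "aneurysm_reserved", "aneurysm_removed")

#' Parametric fistula geometry specification
#'
#' Describes an idealized coronary arterial fistula with a terminal aneurysm,
#' branching at a right angle from a straight parent vessel (the aorta). The
#' morphological parameters mirror the quantities used to characterise
#' patient anatomy: fistula entrance diameter `D_E`, fistula length `L_F`
#' (junction to terminus, including the aneurysm), aneurysm maximum diameter
#' `D_MA` and aneurysm length `L_A`. An optional coronary side branch of
#' width `D_branch` taps off the distal fistula just proximal to the
#' aneurysm and runs to the domain edge; it stands in for the coronary
#' tree that remains fed through the fistula-bearing artery.
#'
#' @param D_E fistula entrance diameter (mm).
#' @param L_F fistula centerline length (mm), junction to terminus.
#' @param D_MA aneurysm maximum diameter (mm); must be >= `D_E`.
#' @param L_A aneurysm length (mm); `0` means no aneurysm.
#' @param D_aorta parent-vessel diameter (mm).
#' @param L_aorta parent-vessel length (mm); also the domain width.
#' @param occlusion_mode one of `"untreated"` (fistula outlet open),
#'   `"aneurysm_reserved"` (distal occlusion: fistula outlet walled, aneurysm
#'   retained) or `"aneurysm_removed"` (proximal occlusion: terminal segment
#'   including the aneurysm converted to solid).
#' @param cell_size grid spacing (mm). At least 8 cells must span `D_E`.
#' @param D_branch coronary side-branch width (mm); `0` disables the branch.
#' @param branch_offset distance (mm) from the aorta junction to the branch
#'   take-off (its proximal edge). The branch leaves the proximal fistula,
#'   as coronary branches leave the fistula-bearing artery close to its
#'   origin; the proximal (aneurysm-removed) occlusion plane sits just
#'   proximal of it, so proximal occlusion sacrifices the branch supply.
#' @return an object of class `geometry_spec`.
#' @seealso [build_fistula_geometry()]
#' @export
geometry_spec <- function(D_E, L_F, D_MA = D_E, L_A = 0,
                          D_aorta = 25, L_aorta = 160,
                          occlusion_mode = "untreated",
                          cell_size = D_E / 8,
                          D_branch = 0, branch_offset = 2 * D_E) {
  occlusion_mode <- match.arg(occlusion_mode, OCCLUSION_MODES)
  stopifnot(is.numeric(D_E), is.numeric(L_F), is.numeric(D_MA), is.numeric(L_A))
  if (D_E <= 0) stop("D_E must be positive")
  if (L_A < 0) stop("L_A must be non-negative")
  if (L_F <= L_A) stop("L_F must exceed L_A (fistula longer than its aneurysm)")
  if (D_MA < D_E) stop("D_MA must be >= D_E: the aneurysm is a dilation of the fistula")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (D_aorta <= 0 || L_aorta <= 0) stop("parent-vessel dimensions must be positive")
  if (D_branch < 0) stop("D_branch must be non-negative")
  if (D_branch > 0 && L_F - branch_offset - D_branch <= L_A) {
    stop("branch must take off the fistula channel proximal of the aneurysm")
  }
  if (D_E / cell_size < 8 - 1e-9) {
    stop(sprintf(
      "resolution floor violated: only %.2f cells span D_E = %g mm at cell_size = %g mm (need >= 8)",
      D_E / cell_size, D_E, cell_size
    ))
  }
  structure(
    list(
      D_E = D_E, L_F = L_F, D_MA = D_MA, L_A = L_A,
      D_aorta = D_aorta, L_aorta = L_aorta,
      occlusion_mode = occlusion_mode, cell_size = cell_size,
      D_branch = D_branch, branch_offset = branch_offset
    ),
    class = "geometry_spec"
  )
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat("Fistula geometry spec (mm):\n")
  cat(sprintf(
    "  D_E %.3g  L_F %.4g  D_MA %.3g  L_A %.3g  D_aorta %.3g  L_aorta %.4g\n",
    x$D_E, x$L_F, x$D_MA, x$L_A, x$D_aorta, x$L_aorta
  ))
  cat(sprintf(
    "  occlusion: %s  cell_size %.3g  D_branch %.3g\n",
    x$occlusion_mode, x$cell_size, x$D_branch
  ))
  invisible(x)
}

# rectangle membership of cell centers; rect = c(x0, x1, y0, y1)
.in_rect <- function(xc, yc, rect) {
  outer(xc >= rect[1] & xc <= rect[2], yc >= rect[3] & yc <= rect[4], `&`)
}

#' Rasterize a fistula geometry to a labelled structured grid
#'
#' Builds the 2D domain: a horizontal parent vessel (aorta) along the top of
#' the domain, a vertical fistula channel of width `D_E` descending from it,
#' a terminal aneurysm bulge of width `D_MA` and length `L_A` at the fistula
#' terminus (domain bottom), and optionally a horizontal coronary side branch
#' leaving the proximal fistula (near its origin, `branch_offset` below the
#' junction) and running to the right domain edge. Cells are
#' labelled fluid/solid, each fluid cell carries a region tag (`aorta`,
#' `fistula`, `aneurysm`), and every fluid-adjacent face carries exactly one
#' boundary label.
#'
#' Occlusion variants relabel/convert only the fistula terminal segment:
#' `aneurysm_reserved` turns the fistula outlet faces into wall;
#' `aneurysm_removed` additionally converts the terminal segment (aneurysm,
#' branch and neck distal of the occlusion plane) to solid.
#'
#' @param spec a [geometry_spec()].
#' @return an object of class `domain_grid` with fields `nx`, `ny`, `h`
#'   (spacing, mm), `fluid` (logical `nx x ny`), `region` (integer matrix,
#'   `NA` for solid cells, levels [REGION_LEVELS]), `u_type`/`v_type`
#'   (face label codes) and the originating `spec`.
#' @export
build_fistula_geometry <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  h <- spec$cell_size
  W <- spec$L_aorta
  H <- spec$L_F + spec$D_aorta
  nx <- as.integer(round(W / h))
  ny <- as.integer(round(H / h))
  if (abs(nx * h - W) > 1e-9 * W || abs(ny * h - H) > 1e-9 * H) {
    # domain is padded to a whole number of cells; shapes are center-tested
    nx <- as.integer(ceiling(W / h - 1e-9))
    ny <- as.integer(ceiling(H / h - 1e-9))
  }
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h

  x_f <- W / 2 - spec$D_E / 2          # fistula left edge
  x_c <- x_f + spec$D_E / 2            # fistula axis
  gap <- 2 * h                         # occlusion-plane stand-off
  y_br1 <- spec$L_F - spec$branch_offset   # branch proximal (top) edge
  y_br0 <- y_br1 - spec$D_branch
  has_branch <- spec$D_branch > 0

  aorta_rect <- c(0, W, spec$L_F, H)
  chan_rect <- c(x_f, x_f + spec$D_E, spec$L_A, spec$L_F)
  ane_rect <- c(x_c - spec$D_MA / 2, x_c + spec$D_MA / 2, 0, spec$L_A)
  br_rect <- c(x_f + spec$D_E, W, y_br0, y_br1)

  in_aorta <- .in_rect(xc, yc, aorta_rect)
  in_chan <- .in_rect(xc, yc, chan_rect)
  in_ane <- if (spec$L_A > 0) .in_rect(xc, yc, ane_rect) else
    matrix(FALSE, nx, ny)
  in_br <- if (has_branch) .in_rect(xc, yc, br_rect) else
    matrix(FALSE, nx, ny)

  fluid <- in_aorta | in_chan | in_ane | in_br
  region <- matrix(NA_integer_, nx, ny)
  region[in_chan] <- 2L
  region[in_ane] <- 3L
  # the branch is coronary-arterial territory, not fistula: it joins the
  # "rest of the domain" region with the parent vessel (the stasis analysis
  # divides the domain into the fistula regions and the rest)
  region[in_br] <- 1L
  region[in_aorta] <- 1L   # aorta strip wins at the junction row

  # occlusion plane for the proximal (aneurysm-removed) variant: proximal to
  # both the aneurysm and the branch take-off
  y_occl <- if (has_branch) y_br1 + gap else spec$L_A + gap
  if (spec$occlusion_mode == "aneurysm_removed") {
    cut <- outer(rep(TRUE, nx), yc < y_occl, `&`)
    fluid[cut] <- FALSE
    region[cut] <- NA_integer_
  }

  grid <- .classify_faces(
    nx = nx, ny = ny, h = h, fluid = fluid, region = region,
    spec = spec, xc = xc, yc = yc, x_c = x_c
  )
  .validate_grid(grid)
  grid
}

# assign one boundary label to every fluid-adjacent face
.classify_faces <- function(nx, ny, h, fluid, region, spec, xc, yc, x_c) {
  pad_x <- rbind(FALSE, fluid, FALSE)          # (nx+2) x ny
  u_l <- pad_x[1:(nx + 1), , drop = FALSE]     # cell left of each u face
  u_r <- pad_x[2:(nx + 2), , drop = FALSE]
  u_type <- matrix(FACE_INACTIVE, nx + 1, ny)
  u_type[u_l & u_r] <- FACE_INTERIOR
  u_type[xor(u_l, u_r)] <- FACE_WALL

  pad_y <- cbind(FALSE, fluid, FALSE)          # nx x (ny+2)
  v_b <- pad_y[, 1:(ny + 1), drop = FALSE]
  v_t <- pad_y[, 2:(ny + 2), drop = FALSE]
  v_type <- matrix(FACE_INACTIVE, nx, ny + 1)
  v_type[v_b & v_t] <- FACE_INTERIOR
  v_type[xor(v_b, v_t)] <- FACE_WALL

  # inlet: left domain edge, aorta strip
  left_fluid <- fluid[1, ]
  u_type[1, left_fluid] <- FACE_INLET
  # right domain edge: aortic outlet (aorta rows), coronary outlet (branch rows)
  right_fluid <- fluid[nx, ]
  is_aorta_row <- yc >= spec$L_F
  u_type[nx + 1, right_fluid & is_aorta_row] <- FACE_AORTIC_OUTLET
  u_type[nx + 1, right_fluid & !is_aorta_row] <- FACE_CORONARY_OUTLET
  # fistula outlet: bottom edge, D_E-wide drainage segment on the axis,
  # untreated variant only
  if (spec$occlusion_mode == "untreated") {
    bottom_fluid <- fluid[, 1]
    seg <- abs(xc - x_c) <= spec$D_E / 2
    v_type[bottom_fluid & seg, 1] <- FACE_FISTULA_OUTLET
  }

  structure(
    list(
      nx = nx, ny = ny, h = h, fluid = fluid, region = region,
      u_type = u_type, v_type = v_type, spec = spec,
      xc = xc, yc = yc
    ),
    class = "domain_grid"
  )
}

.validate_grid <- function(grid) {
  if (!any(grid$fluid)) stop("grid has no fluid cells")
  if (any(grid$fluid & is.na(grid$region))) {
    stop("internal error: fluid cell without a region tag")
  }
  n_comp <- .count_components(grid$fluid)
  if (n_comp != 1L) {
    stop(sprintf("fluid region is not 4-connected: %d components", n_comp))
  }
  mode <- grid$spec$occlusion_mode
  n_fout <- sum(grid$v_type == FACE_FISTULA_OUTLET) +
    sum(grid$u_type == FACE_FISTULA_OUTLET)
  if (mode == "untreated" && n_fout == 0) {
    stop("untreated variant must expose a fistula outlet")
  }
  if (mode != "untreated" && n_fout > 0) {
    stop("occluded variants must not expose a fistula outlet")
  }
  if (mode == "aneurysm_removed" &&
      any(grid$region == 3L, na.rm = TRUE)) {
    stop("aneurysm_removed variant retains aneurysm cells")
  }
  invisible(grid)
}

# 4-connected component count via label propagation (grids are small)
.count_components <- function(fluid) {
  nx <- nrow(fluid); ny <- ncol(fluid)
  lab <- matrix(0L, nx, ny)
  nid <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!fluid[i, j] || lab[i, j] != 0L) next
    nid <- nid + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nid
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- ci + d[1]; nj <- cj + d[2]
        if (ni >= 1L && ni <= nx && nj >= 1L && nj <= ny &&
            fluid[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nid
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  nid
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf(
    "Domain grid %d x %d cells, spacing %.3g mm (%s variant)\n",
    x$nx, x$ny, x$h, x$spec$occlusion_mode
  ))
  counts <- table(factor(REGION_LEVELS[x$region[x$fluid]], levels = REGION_LEVELS))
  cat(sprintf("  fluid cells: %d (%s)\n", sum(x$fluid),
              paste(sprintf("%s %d", names(counts), counts), collapse = ", ")))
  labs <- c(inlet = FACE_INLET, aortic_outlet = FACE_AORTIC_OUTLET,
            coronary_outlet = FACE_CORONARY_OUTLET,
            fistula_outlet = FACE_FISTULA_OUTLET)
  n <- vapply(labs, function(code) {
    sum(x$u_type == code) + sum(x$v_type == code)
  }, integer(1))
  cat(sprintf("  boundary faces: %s\n",
              paste(sprintf("%s %d", names(n), n), collapse = ", ")))
  invisible(x)
}

#' Measure of a tagged region
#'
#' Planar area of the cells carrying a region tag times the unit (1 mm)
#' out-of-plane depth, in mm^3 equivalent. Following the convention that the
#' fistula volume includes its terminal aneurysm, `region = "fistula"` sums
#' fistula and aneurysm cells.
#'
#' @param grid a `domain_grid`.
#' @param region one of `"aorta"`, `"fistula"`, `"aneurysm"`.
#' @return measure in mm^3 equivalent (area in mm^2 x 1 mm depth).
#' @export
region_measure <- function(grid, region) {
  stopifnot(inherits(grid, "domain_grid"))
  if (!region %in% REGION_LEVELS) {
    stop(sprintf("unknown region tag '%s'", region))
  }
  code <- match(region, REGION_LEVELS)
  codes <- if (region == "fistula") c(2L, 3L) else code
  n <- sum(grid$region %in% codes, na.rm = TRUE)
  n * grid$h^2
}

#' Straight-channel grid for verification studies
#'
#' A rectangular channel spanning the whole domain: inlet on the left edge,
#' a single aortic outlet on the right edge, no-slip walls top and bottom.
#' Used by the Poiseuille and plug-flow verification fixtures.
#'
#' @param length,height channel dimensions (mm).
#' @param cell_size grid spacing (mm).
#' @param region region tag applied to every cell (default `"aorta"`; use
#'   `"fistula"` when the channel plays the role of the fistula in washout
#'   studies).
#' @return a `domain_grid`.
#' @export
channel_grid <- function(length, height, cell_size, region = "aorta") {
  stopifnot(length > 0, height > 0, cell_size > 0)
  region_code <- match(match.arg(region, REGION_LEVELS), REGION_LEVELS)
  nx <- as.integer(round(length / cell_size))
  ny <- as.integer(round(height / cell_size))
  fluid <- matrix(TRUE, nx, ny)
  regm <- matrix(as.integer(region_code), nx, ny)
  spec <- structure(
    list(
      D_E = height, L_F = length, D_MA = height, L_A = 0,
      D_aorta = height, L_aorta = length,
      occlusion_mode = "untreated", cell_size = cell_size, D_branch = 0
    ),
    class = "geometry_spec"
  )
  u_type <- matrix(FACE_INTERIOR, nx + 1, ny)
  u_type[1, ] <- FACE_INLET
  u_type[nx + 1, ] <- FACE_AORTIC_OUTLET
  v_type <- matrix(FACE_INTERIOR, nx, ny + 1)
  v_type[, 1] <- FACE_WALL
  v_type[, ny + 1] <- FACE_WALL
  structure(
    list(
      nx = nx, ny = ny, h = cell_size, fluid = fluid, region = regm,
      u_type = u_type, v_type = v_type, spec = spec,
      xc = (seq_len(nx) - 0.5) * cell_size,
      yc = (seq_len(ny) - 0.5) * cell_size
    ),
    class = "domain_grid"
  )
}
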