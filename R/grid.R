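#' Spatial grid specification
#'
#' Defines the voxel geometry shared by every spatial map: square ML x DV
#' bins within a coronal section, replicated over evenly spaced
#' anterior-posterior (AP) sections. Defaults reproduce the standard
#' analysis grid: 50 um bins, 36 x 36 bins per section, 12 sections at
#' 100 um AP intervals (1.8 x 1.8 mm per section).
#'
#' Voxels are enumerated section-major, then DV row, then ML column
#' (row-major within a section), matching the unrolling used by
#' [section_to_grid_vector()].
#'
#' @param bin_size_um Bin edge length in um (ML and DV).
#' @param n_ml,n_dv Number of bins along the medial-lateral and
#'   dorsal-ventral axes.
#' @param n_sections Number of AP sections.
#' @param ap_interval_um AP spacing between consecutive sections, um.
#' @param origin Numeric length-2, (ML, DV) position in um of the lower
#'   corner of bin (row 1, col 1) relative to the cropped image frame.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(bin_size_um = 50, n_ml = 36, n_dv = 36,
                      n_sections = 12, ap_interval_um = 100,
                      origin = c(0, 0)) {
  if (!is.numeric(bin_size_um) || bin_size_um <= 0)
    stop("bin_size_um must be > 0", call. = FALSE)
  counts <- c(n_ml = n_ml, n_dv = n_dv, n_sections = n_sections)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("n_ml, n_dv and n_sections must be integer counts >= 1", call. = FALSE)
  if (ap_interval_um <= 0) stop("ap_interval_um must be > 0", call. = FALSE)
  if (length(origin) != 2 || !is.numeric(origin))
    stop("origin must be a numeric (ML, DV) pair", call. = FALSE)
  structure(list(
    bin_size_um = bin_size_um,
    n_ml = as.integer(n_ml), n_dv = as.integer(n_dv),
    n_sections = as.integer(n_sections),
    ap_interval_um = ap_interval_um,
    origin = as.numeric(origin)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d bins of %g um, %d sections (%g um apart); %d voxels\n",
              x$n_ml, x$n_dv, x$bin_size_um, x$n_sections,
              x$ap_interval_um, n_voxels(x)))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid A [grid_spec()].
#' @return Integer voxel count (`n_ml * n_dv * n_sections`).
#' @export
n_voxels <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_ml * grid$n_dv * grid$n_sections
}

#' Voxel index table
#'
#' Enumerates every voxel of the grid in vector order (section-major,
#' row-major within a section) together with its 1-based (section, row,
#' col) coordinates and its stable id `s{sec}_r{row}_c{col}` (0-based in
#' the id string, for interoperability with on-disk headers).
#'
#' @param grid A [grid_spec()].
#' @return A data.frame with columns `voxel`, `section`, `row`, `col`, `id`.
#' @export
voxel_index_table <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  sec <- rep(seq_len(grid$n_sections), each = grid$n_dv * grid$n_ml)
  row <- rep(rep(seq_len(grid$n_dv), each = grid$n_ml), times = grid$n_sections)
  col <- rep(seq_len(grid$n_ml), times = grid$n_dv * grid$n_sections)
  data.frame(
    voxel = seq_along(sec), section = sec, row = row, col = col,
    id = sprintf("s%d_r%d_c%d", sec - 1L, row - 1L, col - 1L),
    stringsAsFactors = FALSE
  )
}

#' Map AP positions (mm) to grid sections
#'
#' Assigns each AP coordinate to the nearest of the grid's reference
#' sections; exact midpoints resolve toward the anterior (lower index)
#' section.
#'
#' @param ap_mm Numeric AP positions in mm.
#' @param grid A [grid_spec()].
#' @param ap0_mm AP position (mm) of section 1.
#' @return Integer section indices in `1:n_sections`.
#' @export
ap_mm_to_section <- function(ap_mm, grid, ap0_mm = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  step <- grid$ap_interval_um / 1000
  k <- (ap_mm - ap0_mm) / step          # 0-based fractional section
  # nearest section, ties (x.5) toward anterior: use ceiling(k - 0.5)
  idx <- as.integer(ceiling(k - 0.5)) + 1L
  pmin(pmax(idx, 1L), grid$n_sections)
}

grids_conformant <- function(a, b) {
  identical(unclass(a)[c("bin_size_um", "n_ml", "n_dv", "n_sections")],
            unclass(b)[c("bin_size_um", "n_ml", "n_dv", "n_sections")])
}
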