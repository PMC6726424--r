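#' Probability-density map of a labeled cell population
#'
#' Counts the population's cells in the grid's bins (same half-open
#' binning convention as [bin_spots()], per AP section) and normalizes by
#' the total in-grid cell count, yielding a per-voxel probability
#' distribution. Out-of-grid cells are dropped and reported.
#'
#' @param cells data.frame with columns `x_um`, `y_um`, `ap_section` and
#'   `population` (a [simulate_projection_cells()] table or an imported
#'   registered-cell table).
#' @param population Population label to map.
#' @param grid A [grid_spec()].
#' @param mirror_ml If `TRUE`, cells are reflected about the grid's ML
#'   center onto the left hemisphere before binning (for bilateral
#'   populations); off by default.
#' @return An object of class `probability_map`: list with `p` (per-voxel
#'   vector summing to 1), `population`, `n_cells`, `n_dropped`, `grid`,
#'   `voxel_ids`.
#' @export
density_map <- function(cells, population, grid, mirror_ml = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  sel <- cells$population == population
  if (!any(sel))
    stop(sprintf("degenerate input: no cells in population '%s'", population),
         call. = FALSE)
  cc <- cells[sel, , drop = FALSE]
  if (mirror_ml) {
    center <- grid$origin[1] + grid$n_ml * grid$bin_size_um / 2
    cc$x_um <- center - abs(cc$x_um - center)
    message(sprintf("mirroring %d cells onto one hemisphere", nrow(cc)))
  }
  nv <- n_voxels(grid)
  counts <- numeric(nv)
  dropped <- 0L
  npersec <- grid$n_dv * grid$n_ml
  for (s in unique(cc$ap_section)) {
    rows <- cc[cc$ap_section == s, , drop = FALSE]
    if (!(s %in% seq_len(grid$n_sections))) {
      dropped <- dropped + nrow(rows)
      next
    }
    h <- bin_spots(spot_set(data.frame(x_um = rows$x_um, y_um = rows$y_um)),
                   grid)
    counts[(s - 1) * npersec + seq_len(npersec)] <-
      counts[(s - 1) * npersec + seq_len(npersec)] + as.vector(t(h$counts))
    dropped <- dropped + h$dropped
  }
  total <- sum(counts)
  if (total == 0)
    stop("degenerate input: every cell fell outside the grid", call. = FALSE)
  structure(list(p = counts / total, population = population,
                 n_cells = as.integer(total), n_dropped = dropped,
                 grid = grid, voxel_ids = voxel_index_table(grid)$id),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> '%s': %d cells (%d dropped) over %d voxels\n",
              x$population, x$n_cells, x$n_dropped, length(x$p)))
  invisible(x)
}

#' Pairwise correlations between population density maps
#'
#' Pearson correlation between the flattened probability vectors of every
#' pair of maps; the diagonal is 1. An optional voxel mask restricts the
#' comparison to a voxel subset (e.g. the marker-masked bins).
#'
#' @param maps List of >= 2 [density_map()] results on the same grid.
#' @param mask Optional [build_marker_mask()] result.
#' @return Symmetric correlation matrix named by population.
#' @export
pairwise_map_correlation <- function(maps, mask = NULL) {
  if (length(maps) < 2) stop("need >= 2 maps", call. = FALSE)
  g <- maps[[1]]$grid
  if (!all(vapply(maps, function(m) grids_conformant(m$grid, g), logical(1))))
    stop("maps are on different grids", call. = FALSE)
  keep <- rep(TRUE, length(maps[[1]]$p))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voxel_mask"))
    keep <- maps[[1]]$voxel_ids %in% mask$voxel_ids[mask$keep]
  }
  n <- length(maps)
  labs <- vapply(maps, function(m) m$population, character(1))
  out <- diag(1, n)
  dimnames(out) <- list(labs, labs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out[i, j] <- out[j, i] <- pearson(maps[[i]]$p[keep], maps[[j]]$p[keep])
  }
  out
}

#' Fraction of a population lying inside a subtype's correlation domain
#'
#' Sums the population's probability mass over the voxels where the
#' subtype's spatial correlation exceeds `r_threshold`; voxels absent from
#' the (masked) correlation map contribute nothing. The result lies in
#' [0, 1] and quantifies the overlap between a projection-defined
#' population and a transcriptomic subtype's spatial domain.
#'
#' @param map A [density_map()] result.
#' @param subtype_map A [correlation_map()].
#' @param subtype Subtype id.
#' @param r_threshold Strict threshold on r (default 0.1).
#' @return Scalar overlap fraction.
#' @export
overlap_fraction <- function(map, subtype_map, subtype, r_threshold = 0.1) {
  stopifnot(inherits(map, "probability_map"),
            inherits(subtype_map, "correlation_map"))
  s <- match(subtype, subtype_map$subtype_ids)
  if (is.na(s))
    stop(sprintf("unknown subtype '%s'", subtype), call. = FALSE)
  if (!grids_conformant(map$grid, subtype_map$grid))
    stop("map grids differ", call. = FALSE)
  r <- subtype_map$r[s, ]
  hot <- subtype_map$voxel_ids[is.finite(r) & r > r_threshold]
  sum(map$p[map$voxel_ids %in% hot])
}

#' Density maps of FISH-positive cells per probe category
#'
#' Applies [density_map()] to each category's positive-cell coordinates,
#' normalizing each map to its own total count.
#'
#' @param cells_by_category Named list of data.frames with `x_um`, `y_um`,
#'   `ap_section`.
#' @param grid A [grid_spec()].
#' @param mirror_ml Passed to [density_map()].
#' @return Named list of [density_map()] results.
#' @export
fish_positive_density <- function(cells_by_category, grid, mirror_ml = FALSE) {
  if (is.null(names(cells_by_category)))
    stop("cells_by_category must be a named list", call. = FALSE)
  lapply(stats::setNames(names(cells_by_category), names(cells_by_category)),
         function(nm) {
           cc <- cells_by_category[[nm]]
           cc$population <- nm
           density_map(cc, nm, grid, mirror_ml = mirror_ml)
         })
}
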