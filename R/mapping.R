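#' Restrict a profile and a spatial matrix to their shared genes
#'
#' Both inputs are subset to the intersection of their gene sets, in the
#' profile's gene order, and the shared count is reported.
#'
#' @param profile A [cluster_profile()].
#' @param matrix A `spatial_matrix`.
#' @return List with elements `profile` and `matrix`, gene-aligned.
#' @export
intersect_genes <- function(profile, matrix) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(matrix, "spatial_matrix"))
  shared <- intersect(profile$gene_ids, matrix$gene_ids)
  if (length(shared) == 0)
    stop("degenerate input: no shared genes between profile and matrix",
         call. = FALSE)
  message(sprintf("%d shared genes between profile and spatial matrix",
                  length(shared)))
  profile$values <- profile$values[shared, , drop = FALSE]
  profile$gene_ids <- shared
  sel <- match(shared, matrix$gene_ids)
  matrix$values <- matrix$values[sel, , drop = FALSE]
  matrix$gene_ids <- shared
  list(profile = profile, matrix = matrix)
}

#' Z-score matrix rows
#'
#' Centers each row and scales it to unit sample (n-1) standard deviation
#' using its finite entries, producing the normalized expression scores
#' fed to the correlation stage. Rows that are constant (or have fewer
#' than 2 finite entries) become all-0 (`treat_constant = "zero"`) or
#' all-`NA` (`"nan"`); missing entries stay missing.
#'
#' @param values Numeric matrix.
#' @param treat_constant `"zero"` or `"nan"`.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(values, treat_constant = c("zero", "nan")) {
  treat_constant <- match.arg(treat_constant)
  out <- values
  for (g in seq_len(nrow(values))) {
    x <- values[g, ]
    f <- is.finite(x)
    s <- if (sum(f) >= 2) stats::sd(x[f]) else 0
    if (is.na(s) || s == 0) {
      out[g, f] <- if (treat_constant == "zero") 0 else NA_real_
    } else {
      out[g, f] <- (x[f] - mean(x[f])) / s
    }
  }
  out
}

#' Pearson product-moment correlation (pairwise-complete)
#'
#' Computes r by the explicit sum formula over the pairwise-complete
#' entries (both finite). Returns `NA` when fewer than 3 complete pairs
#' remain or either vector is constant on the complete set.
#'
#' @param x,y Equal-length numeric vectors.
#' @return The correlation coefficient, or `NA`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  f <- is.finite(x) & is.finite(y)
  n <- sum(f)
  if (n < 3) return(NA_real_)
  x <- x[f]; y <- y[f]
  xc <- x - sum(x) / n
  yc <- y - sum(y) / n
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  sum(xc * yc) / den
}

#' Correlate subtype profiles with every spatial bin
#'
#' For each subtype s and voxel v, computes the Pearson correlation across
#' the shared genes between the subtype's profile column and the voxel's
#' expression column. With the default normalization both inputs are
#' per-gene z-scored first (the profile across subtypes, the matrix across
#' voxels), putting the two modalities on a common per-gene scale; `"raw"`
#' correlates the unnormalized columns for sensitivity analysis.
#'
#' @param profile A gene-aligned [cluster_profile()] (see
#'   [intersect_genes()]).
#' @param matrix The gene-aligned `spatial_matrix`.
#' @param normalize `"zscore"` (default) or `"raw"`.
#' @return An object of class `correlation_map`: list with `r`
#'   (subtypes x voxels), `n_genes_used` (per voxel), `subtype_ids`,
#'   `grid`, `voxel_ids`, `voxel_index`.
#' @export
correlation_map <- function(profile, matrix, normalize = c("zscore", "raw")) {
  stopifnot(inherits(profile, "cluster_profile"),
            inherits(matrix, "spatial_matrix"))
  normalize <- match.arg(normalize)
  if (!identical(profile$gene_ids, matrix$gene_ids))
    stop("inputs are not gene-aligned; call intersect_genes() first",
         call. = FALSE)
  P <- profile$values
  M <- matrix$values
  if (normalize == "zscore") {
    P <- zscore_rows(P)
    M <- zscore_rows(M)
  }
  nv <- ncol(M)
  ns <- ncol(P)
  r <- base::matrix(NA_real_, ns, nv,
                    dimnames = list(profile$subtype_ids, NULL))
  n_used <- integer(nv)
  fP <- is.finite(P)
  complete_P <- all(fP)
  for (v in seq_len(nv)) {
    m <- M[, v]
    fm <- is.finite(m)
    n_used[v] <- sum(fm & (if (complete_P) TRUE else rowSums(fP) == ns))
    for (s in seq_len(ns)) r[s, v] <- pearson(P[, s], m)
  }
  structure(list(r = r, n_genes_used = n_used,
                 subtype_ids = profile$subtype_ids,
                 grid = matrix$grid, voxel_ids = matrix$voxel_ids,
                 voxel_index = matrix$voxel_index),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d subtypes x %d voxels (finite r: %d)\n",
              nrow(x$r), ncol(x$r), sum(is.finite(x$r))))
  invisible(x)
}

#' Reshape one subtype's correlation map onto the grid
#'
#' Places the (possibly masked) voxel values back into per-section
#' n_dv x n_ml matrices via the voxel index; voxels absent from the map
#' (masked out) are `NA`.
#'
#' @param map A [correlation_map()].
#' @param subtype Subtype id.
#' @return List of `n_sections` matrices.
#' @export
reshape_map <- function(map, subtype) {
  stopifnot(inherits(map, "correlation_map"))
  s <- match(subtype, map$subtype_ids)
  if (is.na(s))
    stop(sprintf("unknown subtype '%s'", subtype), call. = FALSE)
  grid <- map$grid
  full <- rep(NA_real_, n_voxels(grid))
  full[map$voxel_index$voxel] <- map$r[s, ]
  grid_vector_to_sections(full, grid)
}

# NA-aware Gaussian smoothing by normalized convolution
smooth_nan <- function(m, sd_bins) {
  f <- is.finite(m)
  v <- ifelse(f, m, 0)
  num <- gaussian_filter(v, sd_bins)
  den <- gaussian_filter(ifelse(f, 1, 0) * 1.0, sd_bins)
  out <- ifelse(den > 0 & f, num / den, NA_real_)
  matrix(out, nrow(m), ncol(m))
}

#' Prepare correlation grids for display
#'
#' Applies the display convention used for subtype maps: bins with
#' correlation at or below `r_threshold` are made transparent (`NA`), then
#' each section is smoothed with a 2D Gaussian (`smooth_sd_bins` SD,
#' missing-aware normalized convolution). Display-only: the result is
#' never fed back into quantitative operations.
#'
#' @param grids List of per-section matrices from [reshape_map()].
#' @param r_threshold Strict lower threshold (default 0.1).
#' @param smooth_sd_bins Gaussian SD in bins (0 = thresholding only).
#' @return List of display matrices.
#' @export
render_map <- function(grids, r_threshold = 0.1, smooth_sd_bins = 1) {
  if (r_threshold < -1 || r_threshold > 1)
    stop("r_threshold must lie in [-1, 1]", call. = FALSE)
  lapply(grids, function(m) {
    m[!is.finite(m) | m <= r_threshold] <- NA_real_
    if (smooth_sd_bins > 0 && any(is.finite(m)))
      m <- smooth_nan(m, smooth_sd_bins)
    m
  })
}
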