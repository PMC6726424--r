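#' Average replicate grid vectors for one gene
#'
#' Element-wise mean over replicates, ignoring missing (`NA`) entries from
#' missing ISH sections; an entry is `NA` only where every replicate is
#' missing. Permutation-invariant in the replicate list.
#'
#' @param vectors List of equal-length numeric vectors.
#' @return A single numeric vector.
#' @export
average_replicates <- function(vectors) {
  if (length(vectors) < 1) stop("need >= 1 replicate", call. = FALSE)
  len <- vapply(vectors, length, integer(1))
  if (length(unique(len)) != 1)
    stop("replicate vectors have unequal lengths", call. = FALSE)
  m <- do.call(rbind, vectors)
  out <- colMeans(m, na.rm = TRUE)
  out[colSums(!is.na(m)) == 0] <- NA_real_
  out
}

#' Assemble the genes x voxels spatial expression matrix
#'
#' Stacks per-gene grid vectors in input order. Genes whose vector is
#' entirely missing are dropped and reported via the `dropped_genes`
#' attribute (and a message).
#'
#' @param per_gene_vectors Named list mapping gene id to a grid vector of
#'   length `n_voxels(grid)`.
#' @param grid A [grid_spec()].
#' @return An object of class `spatial_matrix`: list with `values`
#'   (genes x voxels), `gene_ids`, `grid`, `voxel_ids`, `voxel_index`.
#' @export
build_matrix <- function(per_gene_vectors, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ids <- names(per_gene_vectors)
  if (is.null(ids) || any(ids == ""))
    stop("per_gene_vectors must be a fully named list", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in input", call. = FALSE)
  nv <- n_voxels(grid)
  bad <- which(vapply(per_gene_vectors, length, integer(1)) != nv)
  if (length(bad) > 0)
    stop(sprintf("vector length != %d voxels for gene(s): %s", nv,
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  values <- do.call(rbind, per_gene_vectors)
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na))
    message(sprintf("dropping %d all-missing gene(s): %s", sum(all_na),
                    paste(ids[all_na], collapse = ", ")))
  vt <- voxel_index_table(grid)
  structure(list(values = values[!all_na, , drop = FALSE],
                 gene_ids = ids[!all_na], grid = grid,
                 voxel_ids = vt$id, voxel_index = vt),
            class = "spatial_matrix",
            dropped_genes = ids[all_na])
}

#' @export
print.spatial_matrix <- function(x, ...) {
  cat(sprintf("<spatial_matrix> %d genes x %d voxels\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Define the marker-gene voxel mask
#'
#' Keeps voxels where the marker gene's binned count exceeds `min_count`
#' (missing entries count as 0). With the default `min_count = 0` this
#' removes exactly the bins with no marker expression, the standard Tph2
#' mask.
#'
#' @param matrix A [build_matrix()] result.
#' @param marker Marker gene id (present in the matrix).
#' @param min_count Strict count threshold (keep where count > min_count).
#' @return An object of class `voxel_mask`: list with `keep` (logical per
#'   voxel), `voxel_ids`, `source_gene`, `threshold`.
#' @export
build_marker_mask <- function(matrix, marker, min_count = 0) {
  stopifnot(inherits(matrix, "spatial_matrix"))
  row <- match(marker, matrix$gene_ids)
  if (is.na(row))
    stop(sprintf("marker gene '%s' not in matrix", marker), call. = FALSE)
  v <- matrix$values[row, ]
  v[!is.finite(v)] <- 0
  keep <- v > min_count
  if (!any(keep))
    stop("degenerate mask: no voxel passes the marker threshold",
         call. = FALSE)
  structure(list(keep = keep, voxel_ids = matrix$voxel_ids,
                 source_gene = marker, threshold = min_count),
            class = "voxel_mask")
}

#' Restrict a spatial matrix to masked voxels
#'
#' Keeps the columns whose voxel id is in the mask's kept set; the voxel
#' index is updated accordingly. Matching is by voxel id, so applying the
#' same mask twice equals applying it once.
#'
#' @param matrix A `spatial_matrix`.
#' @param mask A [build_marker_mask()] result.
#' @return The masked `spatial_matrix`.
#' @export
apply_mask <- function(matrix, mask) {
  stopifnot(inherits(matrix, "spatial_matrix"), inherits(mask, "voxel_mask"))
  kept_ids <- mask$voxel_ids[mask$keep]
  sel <- matrix$voxel_ids %in% kept_ids
  matrix$values <- matrix$values[, sel, drop = FALSE]
  matrix$voxel_ids <- matrix$voxel_ids[sel]
  matrix$voxel_index <- matrix$voxel_index[sel, , drop = FALSE]
  matrix
}

#' Filter genes on total expression and mean-normalized variance
#'
#' Keeps genes whose missing-ignoring total is at least `min_total` and
#' whose Fano factor (sample variance / mean, the mean-normalized
#' variance) is at least `min_fano`. Genes with zero mean are always
#' dropped. The dropped ids are attached as the `dropped_genes` attribute
#' and the surviving count is reported.
#'
#' @param matrix A `spatial_matrix`.
#' @param min_total Minimum total count (>= 0).
#' @param min_fano Minimum Fano factor (>= 0).
#' @return The filtered `spatial_matrix`.
#' @export
filter_genes <- function(matrix, min_total = 20, min_fano = 0.7) {
  stopifnot(inherits(matrix, "spatial_matrix"))
  if (min_total < 0 || min_fano < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  v <- matrix$values
  total <- rowSums(v, na.rm = TRUE)
  mu <- rowMeans(v, na.rm = TRUE)
  va <- apply(v, 1, stats::var, na.rm = TRUE)
  fano <- ifelse(mu > 0, va / mu, NA_real_)
  keep <- mu > 0 & total >= min_total & !is.na(fano) & fano >= min_fano
  if (!any(keep))
    stop("degenerate output: no gene passes the filters", call. = FALSE)
  message(sprintf("%d of %d genes survive the expression filters",
                  sum(keep), length(keep)))
  dropped <- matrix$gene_ids[!keep]
  matrix$values <- v[keep, , drop = FALSE]
  matrix$gene_ids <- matrix$gene_ids[keep]
  attr(matrix, "dropped_genes") <- dropped
  matrix
}
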