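#' Downsample a grayscale image by block averaging
#'
#' Reduces both image dimensions by an integer factor using the mean of
#' each factor x factor block (trailing partial blocks are dropped).
#' Block means preserve the intensity scale and, in expectation, the
#' total signal per unit area.
#'
#' @param img Numeric matrix (rows = DV pixels, cols = ML pixels).
#' @param factor Integer reduction factor >= 1.
#' @return Downsampled matrix.
#' @export
downsample_image <- function(img, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be an integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(img)
  if (nrow(img) < factor || ncol(img) < factor)
    stop("image smaller than downsampling factor", call. = FALSE)
  nr <- nrow(img) %/% factor
  nc <- ncol(img) %/% factor
  img <- img[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # block mean via two reshaped column-sum passes (rows, then columns)
  r1 <- matrix(colSums(matrix(img, nrow = factor)), nr, nc * factor)
  t(matrix(colSums(matrix(t(r1), nrow = factor)), nc, nr)) / factor^2
}

#' Estimate the vertical midline of a coronal image
#'
#' Finds the mirror axis maximizing the left-right intensity
#' cross-correlation between the image and its horizontal reflection.
#' Candidate axes lie on the half-integer column lattice; the score of
#' axis c is the sum of products I[, j] * I[, 2c - j] over all column
#' pairs mapped onto each other, computed from the anti-diagonals of the
#' column Gram matrix. Ties are broken toward the image center.
#'
#' @param img Numeric matrix with >= 3 columns.
#' @param smooth_sigma_px Optional Gaussian pre-blur (pixels, 0 = none)
#'   to stabilize the estimate on sparse dotty images.
#' @return The axis column coordinate (possibly half-integer, 1-based).
#' @export
estimate_midline <- function(img, smooth_sigma_px = 0) {
  if (ncol(img) < 3) stop("image needs >= 3 columns", call. = FALSE)
  if (max(img) == min(img))
    stop("degenerate input: constant image has no midline", call. = FALSE)
  if (smooth_sigma_px > 0)
    img <- gaussian_filter(img, smooth_sigma_px)
  cp <- crossprod(img)                   # cp[j, k] = sum_i I[i,j] I[i,k]
  n <- ncol(img)
  jj <- row(cp) + col(cp)                # axis c = (j + k) / 2
  score <- vapply(3:(2 * n - 1), function(s) sum(cp[jj == s]), numeric(1))
  axes <- (3:(2 * n - 1)) / 2            # candidate axes 1.5 .. n - 0.5
  best <- which(score == max(score))
  center <- (n + 1) / 2
  best <- best[order(abs(axes[best] - center), axes[best])][1]
  axes[best]
}

#' Crop a window of fixed physical width centered on the midline
#'
#' Returns a window `round(width_um / px_size_um)` pixels wide centered on
#' the midline column; with an even pixel width the extra pixel falls to
#' the right. Area outside the image is zero-padded; the vertical extent
#' is unchanged.
#'
#' @param img Numeric matrix.
#' @param midline Column coordinate (may be fractional).
#' @param width_um Window width in um (> 0).
#' @param px_size_um Pixel size in um.
#' @return Matrix with `nrow(img)` rows and the requested width.
#' @export
align_and_crop <- function(img, midline, width_um, px_size_um) {
  if (width_um <= 0) stop("width_um must be > 0", call. = FALSE)
  if (midline < 1 || midline > ncol(img))
    stop("midline outside image", call. = FALSE)
  w <- round(width_um / px_size_um)
  start <- floor(midline - w / 2) + 1    # equal sides; extra pixel right
  out <- matrix(0, nrow(img), w)
  src <- (start:(start + w - 1))
  ok <- src >= 1 & src <= ncol(img)
  out[, which(ok)] <- img[, src[ok], drop = FALSE]
  out
}

#' Binarize expression by thresholding
#'
#' `method = "otsu"` derives the threshold from the image histogram
#' (Otsu's criterion, via \pkg{EBImage}); `method = "fixed"` uses the
#' supplied threshold. The mask is `img > threshold`. A constant image
#' under Otsu yields an all-`FALSE` mask with a warning.
#'
#' @param img Numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @return Logical mask with attribute `threshold`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold))
      stop("fixed_threshold required for method = 'fixed'", call. = FALSE)
    thr <- fixed_threshold
  } else {
    lo <- min(img); hi <- max(img)
    if (hi == lo) {
      warning("constant image: Otsu threshold undefined, returning all-FALSE")
      return(structure(matrix(FALSE, nrow(img), ncol(img)), threshold = NA_real_))
    }
    thr <- EBImage::otsu((img - lo) / (hi - lo), range = c(0, 1),
                         levels = 256) * (hi - lo) + lo
  }
  structure(img > thr, threshold = thr)
}

# Gaussian blur with zero boundary (separable, via EBImage::filter2);
# kernel radius clamped so the filter fits small images
gaussian_filter <- function(img, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  r <- min(r, (min(dim(img)) - 1L) %/% 2L)
  if (r < 1) return(img)
  g <- stats::dnorm(-r:r, sd = sigma_px)
  g <- g / sum(g)
  k <- outer(g, g)
  EBImage::filter2(img, k, boundary = 0)
}

# scale-normalized negated-LoG response (bright blobs -> positive peaks)
log_response <- function(img, sigma_px) {
  r <- max(2L, ceiling(4 * sigma_px))
  d2 <- outer((-r:r)^2, (-r:r)^2, "+")
  g <- exp(-d2 / (2 * sigma_px^2))
  k <- -(d2 - 2 * sigma_px^2) / sigma_px^2 * g   # sigma^2-normalized -LoG
  k <- k - mean(k)                               # zero response on flats
  EBImage::filter2(img, k, boundary = 0)
}

#' Detect cell-like spots with a Laplacian-of-Gaussian filter
#'
#' Computes the scale-normalized negated-LoG response at the physical
#' scale `sigma_um`, keeps strict 8-neighborhood local maxima above the
#' response threshold, and applies greedy non-maximum suppression within
#' `min_separation_um`. The response is linear in image intensity, so
#' rescaling the image and `min_response` by the same positive constant
#' leaves detections unchanged; the fractional threshold is scale-free.
#'
#' @param img Numeric matrix (grayscale, cropped frame).
#' @param sigma_um Blob scale, um (> 0).
#' @param px_size_um Pixel size, um.
#' @param min_response Absolute response threshold; when `NULL`, the
#'   threshold is `max(min_response_frac * max(response),
#'   min_response_mad * mad(response))` — the fractional term adapts to
#'   signal strength while the robust MAD floor rejects background-noise
#'   extrema on sections without real expression.
#' @param min_response_frac Fractional response threshold (default 0.05).
#' @param min_response_mad Noise floor in MAD units of the response
#'   (default 14, above the extreme-value range of clipped background noise and below single-cell responses; 0 disables the floor).
#' @param min_separation_um Minimum center-to-center distance, um.
#' @param mask Optional logical matrix (same shape): detections whose
#'   peak pixel falls outside the mask are discarded (binarization gate).
#' @param gene,section Optional labels carried on the result.
#' @return A `spot_set`: data.frame with `x_um`, `y_um`, `response` and
#'   attributes `gene` and `section`. Coordinates are pixel centers in um
#'   in the cropped-image frame.
#' @export
detect_spots <- function(img, sigma_um, px_size_um,
                         min_response = NULL, min_response_frac = 0.05,
                         min_response_mad = 14,
                         min_separation_um = 2 * sigma_um, mask = NULL,
                         gene = NA_character_, section = NA_integer_) {
  if (sigma_um <= 0) stop("sigma_um must be > 0", call. = FALSE)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      response = numeric(0))
  resp <- log_response(img, sigma_um / px_size_um)
  thr <- if (is.null(min_response)) {
    max(min_response_frac * max(resp), min_response_mad * stats::mad(resp))
  } else min_response
  ny <- nrow(resp); nx <- ncol(resp)
  if (max(resp) <= 0 || thr <= 0)
    return(spot_set(empty, gene, section))
  # strict local maxima over the 8-neighborhood
  is_max <- resp >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, ny, nx)
    ri <- max(1, 1 + di):min(ny, ny + di)
    rj <- max(1, 1 + dj):min(nx, nx + dj)
    shifted[ri, rj] <- resp[ri - di, rj - dj, drop = FALSE]
    is_max <- is_max & (resp > shifted |
                          (resp == shifted & (di < 0 | (di == 0 & dj < 0))))
  }
  idx <- which(is_max)
  if (length(idx) == 0) return(spot_set(empty, gene, section))
  i <- (idx - 1L) %% ny + 1L
  j <- (idx - 1L) %/% ny + 1L
  if (!is.null(mask)) {
    keep <- mask[cbind(i, j)]
    i <- i[keep]; j <- j[keep]; idx <- idx[keep]
  }
  if (length(idx) == 0) return(spot_set(empty, gene, section))
  x <- (j - 0.5) * px_size_um
  y <- (i - 0.5) * px_size_um
  r <- resp[cbind(i, j)]
  ord <- order(-r, y, x)                 # deterministic NMS order
  x <- x[ord]; y <- y[ord]; r <- r[ord]
  keep <- logical(length(x))
  for (k in seq_along(x)) {
    if (!any(keep) ||
        min((x[keep] - x[k])^2 + (y[keep] - y[k])^2) >= min_separation_um^2)
      keep[k] <- TRUE
  }
  spot_set(data.frame(x_um = x[keep], y_um = y[keep], response = r[keep]),
           gene, section)
}

#' Construct a spot set
#' @param centroids data.frame with `x_um`, `y_um` (and optionally
#'   `response`).
#' @param gene,section Labels.
#' @return data.frame of class `spot_set` with `gene`/`section` attributes.
#' @export
spot_set <- function(centroids, gene = NA_character_, section = NA_integer_) {
  stopifnot(all(c("x_um", "y_um") %in% names(centroids)))
  structure(as.data.frame(centroids), gene = gene,
            section = as.integer(section),
            class = c("spot_set", "data.frame"))
}

#' Bin spot centroids into a 2D section histogram
#'
#' Counts centroids in the grid's square bins using half-open,
#' lower-inclusive intervals: bin (i, j) covers
#' ML in `[origin + (j-1) b, origin + j b)` and likewise for DV, so a spot
#' exactly on an interior boundary joins the higher-index bin. Spots
#' outside the grid are dropped and reported.
#'
#' @param spots A [spot_set()].
#' @param grid A [grid_spec()].
#' @return A `section_hist`: list with `counts` (n_dv x n_ml), `gene`,
#'   `section`, `offset_dv` (0), and `dropped` (out-of-grid spot count).
#' @export
bin_spots <- function(spots, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  b <- grid$bin_size_um
  j <- floor((spots$x_um - grid$origin[1]) / b) + 1
  i <- floor((spots$y_um - grid$origin[2]) / b) + 1
  ok <- i >= 1 & i <= grid$n_dv & j >= 1 & j <= grid$n_ml
  counts <- matrix(0, grid$n_dv, grid$n_ml)
  if (any(ok)) {
    t <- table(factor(i[ok], levels = seq_len(grid$n_dv)),
               factor(j[ok], levels = seq_len(grid$n_ml)))
    counts <- matrix(as.numeric(t), grid$n_dv, grid$n_ml)
  }
  section_hist(counts, gene = attr(spots, "gene"),
               section = attr(spots, "section"),
               dropped = sum(!ok))
}

#' Construct a section histogram
#' @param counts n_dv x n_ml numeric matrix (all-`NA` marks a missing
#'   section).
#' @param gene,section Labels.
#' @param offset_dv Recorded DV alignment offset (bins).
#' @param dropped Out-of-grid spot count from binning.
#' @return An object of class `section_hist`.
#' @export
section_hist <- function(counts, gene = NA_character_, section = NA_integer_,
                         offset_dv = 0L, dropped = 0L) {
  stopifnot(is.matrix(counts))
  structure(list(counts = counts, gene = gene,
                 section = if (is.null(section)) NA_integer_ else as.integer(section),
                 offset_dv = as.integer(offset_dv),
                 dropped = as.integer(dropped)),
            class = "section_hist")
}

# shift histogram content `offset` bins toward dorsal (decreasing row
# index); vacated rows are zero-filled
shift_dv <- function(counts, offset) {
  out <- matrix(0, nrow(counts), ncol(counts))
  src <- seq_len(nrow(counts)) + offset
  ok <- src >= 1 & src <= nrow(counts)
  out[which(ok), ] <- counts[src[ok], , drop = FALSE]
  out
}

#' Fine alignment along the dorsal-ventral axis
#'
#' Shifts a histogram along DV by the integer offset (within
#' `max_shift_bins`) that maximizes the Pearson correlation of its DV
#' marginal profile with the reference histogram's (typically the Tph2
#' histogram of the same section). A positive offset moves content toward
#' dorsal (decreasing row index); vacated rows are zero-filled. Among
#' ties, the smallest offset magnitude wins. `manual_offset` bypasses the
#' search entirely, standing in for the manual adjustment step.
#'
#' @param hist,reference `section_hist` objects on the same grid shape.
#' @param max_shift_bins Maximum offset magnitude searched.
#' @param manual_offset Optional user-supplied offset (bins) applied
#'   verbatim.
#' @return The shifted `section_hist` with `offset_dv` recorded.
#' @export
fine_align_dv <- function(hist, reference, max_shift_bins = 3,
                          manual_offset = NULL) {
  stopifnot(inherits(hist, "section_hist"), inherits(reference, "section_hist"))
  if (!all(dim(hist$counts) == dim(reference$counts)))
    stop("histogram shapes differ", call. = FALSE)
  if (!is.null(manual_offset)) {
    hist$counts <- shift_dv(hist$counts, manual_offset)
    hist$offset_dv <- as.integer(manual_offset)
    return(hist)
  }
  if (all(!is.finite(hist$counts)) || sum(hist$counts, na.rm = TRUE) == 0) {
    warning("all-zero histogram: DV alignment skipped (offset 0)")
    hist$offset_dv <- 0L
    return(hist)
  }
  if (sum(reference$counts, na.rm = TRUE) == 0)
    stop("reference histogram is empty", call. = FALSE)
  ref_m <- rowSums(reference$counts)
  offsets <- seq(-max_shift_bins, max_shift_bins)
  offsets <- offsets[order(abs(offsets), offsets)]  # prefer small |offset|
  score <- vapply(offsets, function(o) {
    m <- rowSums(shift_dv(hist$counts, o))
    r <- pearson(m, ref_m)
    if (is.na(r)) -Inf else r
  }, numeric(1))
  best <- offsets[which.max(score)]
  hist$counts <- shift_dv(hist$counts, best)
  hist$offset_dv <- as.integer(best)
  hist
}

#' Average a histogram with its left-right reflection
#'
#' Replaces the counts by `(H + mirror_ML(H)) / 2`, enforcing exact ML
#' symmetry (`counts[i, j] == counts[i, n - 1 - j]` bitwise) while
#' preserving the total count.
#'
#' @param hist A `section_hist`.
#' @return The symmetrized `section_hist`.
#' @export
reflect_average <- function(hist) {
  stopifnot(inherits(hist, "section_hist"))
  m <- hist$counts
  hist$counts <- (m + m[, rev(seq_len(ncol(m))), drop = FALSE]) / 2
  hist
}

#' Unroll one experiment's section histograms into a row vector
#'
#' Concatenates the `n_sections` histograms in (section, DV row, ML
#' column) order, row-major within a section. Missing sections are passed
#' as all-`NA` histograms and occupy `NA` runs in the vector. The
#' operation is inverted exactly by [grid_vector_to_sections()].
#'
#' @param hists List of `section_hist` objects (or bare matrices), one per
#'   grid section, in AP order.
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_voxels(grid)`.
#' @export
section_to_grid_vector <- function(hists, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(hists) != grid$n_sections)
    stop(sprintf("expected %d section histograms, got %d",
                 grid$n_sections, length(hists)), call. = FALSE)
  mats <- lapply(hists, function(h) {
    m <- if (inherits(h, "section_hist")) h$counts else h
    if (!is.matrix(m) || !all(dim(m) == c(grid$n_dv, grid$n_ml)))
      stop("section histogram shape does not match grid", call. = FALSE)
    m
  })
  unlist(lapply(mats, function(m) as.vector(t(m))), use.names = FALSE)
}

#' Reshape a grid vector back into per-section matrices
#' @param v Numeric vector of length `n_voxels(grid)`.
#' @param grid A [grid_spec()].
#' @return List of `n_sections` matrices (n_dv x n_ml).
#' @export
grid_vector_to_sections <- function(v, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(v) != n_voxels(grid))
    stop("vector length does not match grid", call. = FALSE)
  npersec <- grid$n_dv * grid$n_ml
  lapply(seq_len(grid$n_sections), function(s) {
    m <- matrix(v[(s - 1) * npersec + seq_len(npersec)],
                grid$n_dv, grid$n_ml, byrow = TRUE)
    m
  })
}
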