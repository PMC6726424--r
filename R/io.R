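#' Default pipeline configuration
#'
#' One flat structured configuration holding every numeric constant of the
#' analysis, so an unedited run reproduces the standard settings: 50 um
#' bins on a 36 x 36 x 12 grid at 100 um AP intervals, downsampling by 2,
#' a ~1 mm midline crop, Otsu binarization, LoG spot detection, the Tph2
#' voxel mask, expression/Fano gene filters, per-gene z-score
#' normalization, the r > 0.1 display threshold with 1-bin Gaussian
#' display smoothing, and the >= 3 puncta FISH positivity rule.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    grid = list(bin_size_um = 50, n_ml = 36L, n_dv = 36L, n_sections = 12L,
                ap_interval_um = 100),
    ish = list(downsample_factor = 2L, crop_width_um = 1000,
               binarize_method = "otsu", fixed_threshold = NA,
               log_sigma_um = 6, log_min_separation_um = 12,
               log_min_response_frac = 0.05, log_min_response_mad = 14,
               midline_smooth_px = 2,
               dv_max_shift_bins = 3L, use_mask_gate = TRUE, ap0_mm = 0),
    matrix = list(marker_gene = "Tph2", mask_min_count = 0,
                  min_total = 20, min_fano = 0.7,
                  filter_before_mask = FALSE),
    mapping = list(normalize = "zscore", r_threshold = 0.1,
                   smooth_sd_bins = 1),
    density = list(mirror_ml = FALSE, mask_correlations = TRUE),
    fish = list(min_puncta = 3L),
    seed = 1L
  )
}

#' Build the grid specification named by a configuration
#' @param config A configuration list (see [default_config()]).
#' @return A [grid_spec()].
#' @export
config_grid <- function(config) {
  g <- config$grid
  grid_spec(bin_size_um = g$bin_size_um, n_ml = g$n_ml, n_dv = g$n_dv,
            n_sections = g$n_sections, ap_interval_um = g$ap_interval_um)
}

#' Read / write a configuration file (YAML)
#' @param path File path.
#' @return `read_config` returns the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  atomic_write(path, function(tmp) yaml::write_yaml(config, tmp))
  invisible(path)
}

# atomic write: emit into a temp file in the target directory, then rename
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not write %s", path), call. = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV (atomic)
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  atomic_write(path, function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA"))
}

#' Read a TSV with schema validation
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numeric; a failing row
#'   is reported by number.
#' @return data.frame.
#' @export
read_tsv_checked <- function(path, required = character(0),
                             numeric_cols = character(0)) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad) > 0)
      stop(sprintf("%s: column '%s' not numeric at row(s) %s", path, col,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read / write a grayscale image (single-channel 32-bit float TIFF)
#' @param path File path.
#' @return `read_image` returns a numeric matrix in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image not found: %s", path), call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname read_image
#' @param img Numeric matrix with values in [0, 1].
#' @export
write_image <- function(img, path) {
  atomic_write(path, function(tmp)
    tiff::writeTIFF(pmin(pmax(img, 0), 1), tmp, bits.per.sample = 32))
}

#' Read / write the image manifest
#'
#' The manifest links every ISH image to its metadata: columns `gene`,
#' `ap_mm` (AP position, mm), `px_size_um`, `path`, and optionally
#' `replicate` (defaults to 1).
#'
#' @param path Manifest TSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_checked(path, required = c("gene", "ap_mm", "px_size_um",
                                            "path"),
                         numeric_cols = c("ap_mm", "px_size_um"))
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}

#' @rdname read_manifest
#' @param manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(manifest, path)
}

#' Read / write a cluster-averaged expression profile (genes x subtypes)
#' @param path TSV path; first column `gene`, remaining columns subtypes.
#' @return `read_profile` returns a [cluster_profile()].
#' @export
read_profile <- function(path) {
  df <- read_tsv_checked(path, required = "gene")
  if (ncol(df) < 2)
    stop(sprintf("%s: no subtype columns", path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene
  cluster_profile(m)
}

#' @rdname read_profile
#' @param profile A [cluster_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "cluster_profile"))
  df <- data.frame(gene = profile$gene_ids, profile$values,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' Read / write a spatial expression matrix as TSV
#'
#' Header: `gene` followed by voxel ids `s{sec}_r{row}_c{col}` (0-based),
#' so a masked matrix keeps its voxel addressing on disk.
#'
#' @param path TSV path.
#' @param grid A [grid_spec()] (the full grid the voxel ids refer to).
#' @return `read_matrix_tsv` returns a `spatial_matrix`.
#' @export
read_matrix_tsv <- function(path, grid) {
  df <- read_tsv_checked(path, required = "gene")
  ids <- setdiff(names(df), "gene")
  vt <- voxel_index_table(grid)
  pos <- match(ids, vt$id)
  if (anyNA(pos))
    stop(sprintf("%s: unknown voxel id(s): %s", path,
                 paste(utils::head(ids[is.na(pos)], 3), collapse = ", ")),
         call. = FALSE)
  values <- as.matrix(df[, ids, drop = FALSE])
  mode(values) <- "numeric"
  rownames(values) <- df$gene
  structure(list(values = values, gene_ids = df$gene, grid = grid,
                 voxel_ids = ids, voxel_index = vt[pos, , drop = FALSE]),
            class = "spatial_matrix")
}

#' @rdname read_matrix_tsv
#' @param matrix A `spatial_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "spatial_matrix"))
  df <- data.frame(gene = matrix$gene_ids, matrix$values,
                   check.names = FALSE, row.names = NULL)
  names(df) <- c("gene", matrix$voxel_ids)
  write_tsv(df, path)
}

#' Read a labeled-cell coordinate table
#' @param path TSV with columns `x_um`, `y_um`, `ap_section`, `population`
#'   (optional `animal`).
#' @return data.frame.
#' @export
read_cell_table <- function(path) {
  df <- read_tsv_checked(path,
                         required = c("x_um", "y_um", "ap_section",
                                      "population"),
                         numeric_cols = c("x_um", "y_um", "ap_section"))
  df$ap_section <- as.integer(df$ap_section)
  df
}

#' Read a per-cell FISH puncta table
#' @param path TSV with columns `cell_id`, `x_um`, `y_um`, `ap_section`
#'   plus one integer puncta column per probe.
#' @return data.frame.
#' @export
read_fish_table <- function(path) {
  read_tsv_checked(path, required = c("cell_id", "x_um", "y_um",
                                      "ap_section"),
                   numeric_cols = c("x_um", "y_um", "ap_section"))
}
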