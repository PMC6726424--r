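#' Process one ISH image into a section histogram
#'
#' The imaging chain for a single gene x section image: block-mean
#' downsampling, midline estimation, fixed-width crop about the midline,
#' binarization, LoG spot detection (gated by the binary mask when
#' configured), and binning into the grid. The grid is centered within
#' the cropped window in both ML and DV.
#'
#' @param img Grayscale matrix.
#' @param px_size_um Pixel size of `img`, um.
#' @param config Configuration list (see [default_config()]).
#' @param gene,section Labels attached to the result.
#' @return A `section_hist` with attribute `n_spots`.
#' @export
process_ish_image <- function(img, px_size_um, config = default_config(),
                              gene = NA_character_, section = NA_integer_) {
  grid <- config_grid(config)
  ish <- config$ish
  ds <- downsample_image(img, ish$downsample_factor)
  px <- px_size_um * ish$downsample_factor
  mid <- estimate_midline(ds, smooth_sigma_px = ish$midline_smooth_px)
  cropped <- align_and_crop(ds, mid, ish$crop_width_um, px)
  bm <- if (identical(ish$binarize_method, "fixed") &&
            is.finite(ish$fixed_threshold)) {
    binarize(cropped, "fixed", fixed_threshold = ish$fixed_threshold)
  } else {
    binarize(cropped, "otsu")
  }
  spots <- detect_spots(cropped, sigma_um = ish$log_sigma_um,
                        px_size_um = px,
                        min_response_frac = ish$log_min_response_frac,
                        min_response_mad = ish$log_min_response_mad,
                        min_separation_um = ish$log_min_separation_um,
                        mask = if (isTRUE(ish$use_mask_gate)) bm else NULL,
                        gene = gene, section = section)
  # center the analysis grid inside the cropped window
  bgrid <- grid
  bgrid$origin <- c((ncol(cropped) * px - grid$n_ml * grid$bin_size_um) / 2,
                    (nrow(cropped) * px - grid$n_dv * grid$bin_size_um) / 2)
  h <- bin_spots(spots, bgrid)
  attr(h, "n_spots") <- nrow(spots)
  h
}

#' Process an image manifest into per-gene grid vectors
#'
#' Runs [process_ish_image()] on every manifest row, fine-aligns each
#' histogram along DV against the marker gene's histogram of the same
#' section (when the marker is present in the manifest), reflection-
#' averages, unrolls each replicate into a grid vector (missing sections
#' become `NA` runs) and averages replicates per gene.
#'
#' @param manifest data.frame (see [read_manifest()]) or a path to one.
#' @param config Configuration list.
#' @param reference_gene DV-alignment reference gene; defaults to the
#'   configured marker gene.
#' @return List with `vectors` (named list gene -> grid vector) and
#'   `audit` (per-image data.frame: gene, replicate, section, n_spots,
#'   dropped, offset_dv).
#' @export
process_manifest <- function(manifest, config = default_config(),
                             reference_gene = config$matrix$marker_gene) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(manifest$replicate)) manifest$replicate <- 1L
  grid <- config_grid(config)
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files) > 0)
    stop(sprintf("manifest references missing image(s): %s",
                 paste(utils::head(missing_files, 3), collapse = ", ")),
         call. = FALSE)
  manifest$section <- ap_mm_to_section(manifest$ap_mm, grid,
                                       ap0_mm = config$ish$ap0_mm)
  hists <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    img <- read_image(manifest$path[k])
    hists[[k]] <- process_ish_image(img, manifest$px_size_um[k], config,
                                    gene = manifest$gene[k],
                                    section = manifest$section[k])
  }
  # reference histograms per section for DV fine alignment
  refs <- list()
  if (!is.null(reference_gene) && reference_gene %in% manifest$gene) {
    for (k in which(manifest$gene == reference_gene))
      refs[[as.character(manifest$section[k])]] <- hists[[k]]
  }
  audit <- manifest[, c("gene", "replicate", "section")]
  audit$n_spots <- NA_integer_; audit$dropped <- NA_integer_
  audit$offset_dv <- 0L
  for (k in seq_along(hists)) {
    ref <- refs[[as.character(manifest$section[k])]]
    if (!is.null(ref) && manifest$gene[k] != reference_gene &&
        sum(ref$counts) > 0) {
      hists[[k]] <- fine_align_dv(hists[[k]], ref,
                                  max_shift_bins = config$ish$dv_max_shift_bins)
    }
    hists[[k]] <- reflect_average(hists[[k]])
    audit$n_spots[k] <- attr(hists[[k]], "n_spots")
    audit$dropped[k] <- hists[[k]]$dropped
    audit$offset_dv[k] <- hists[[k]]$offset_dv
  }
  # one vector per (gene, replicate); NA histograms for missing sections
  na_mat <- matrix(NA_real_, grid$n_dv, grid$n_ml)
  vectors <- list()
  for (g in unique(manifest$gene)) {
    reps <- list()
    for (r in unique(manifest$replicate[manifest$gene == g])) {
      sel <- which(manifest$gene == g & manifest$replicate == r)
      per_sec <- rep(list(na_mat), grid$n_sections)
      for (k in sel) per_sec[[manifest$section[k]]] <- hists[[k]]$counts
      reps[[length(reps) + 1]] <- section_to_grid_vector(per_sec, grid)
    }
    vectors[[g]] <- average_replicates(reps)
  }
  list(vectors = vectors, audit = audit)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates imaging, matrix assembly, masking, gene filtering,
#' subtype correlation mapping, projection-density mapping and FISH
#' quantification as configured, writing every stage's outputs and a
#' machine-readable provenance record under `out_dir`. Deterministic
#' stages are byte-identical on rerun with identical inputs.
#'
#' @param manifest Image manifest (data.frame or TSV path).
#' @param profile Cluster profile ([cluster_profile()] or TSV path).
#' @param config Configuration list.
#' @param cell_tables Optional labeled-cell data.frame (or TSV path) for
#'   projection density maps.
#' @param fish_tables Optional named list of FISH cell tables.
#' @param fish_plan Optional panel plan for [summarize_panel()].
#' @param out_dir Output directory.
#' @return (Invisibly) a list with the in-memory stage results:
#'   `matrix`, `filtered`, `mask`, `corr_map`, `density_maps`,
#'   `pairwise`, `fish_summary`, `audit`, `out_dir`.
#' @export
run_pipeline <- function(manifest, profile, config = default_config(),
                         cell_tables = NULL, fish_tables = NULL,
                         fish_plan = NULL, out_dir = tempfile("raphemap_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config_grid(config)
  if (is.character(profile)) profile <- run_stage("io", read_profile(profile))
  if (is.character(cell_tables))
    cell_tables <- run_stage("io", read_cell_table(cell_tables))

  proc <- run_stage("process-ish", process_manifest(manifest, config))
  write_tsv(proc$audit, file.path(out_dir, "alignment_audit.tsv"))

  mat <- run_stage("build-matrix", build_matrix(proc$vectors, grid))
  write_matrix_tsv(mat, file.path(out_dir, "spatial_matrix.tsv"))

  filtered <- run_stage("filter-matrix", {
    marker <- config$matrix$marker_gene
    mask <- build_marker_mask(mat, marker,
                              min_count = config$matrix$mask_min_count)
    if (isTRUE(config$matrix$filter_before_mask)) {
      m <- filter_genes(mat, config$matrix$min_total, config$matrix$min_fano)
      list(matrix = apply_mask(m, mask), mask = mask)
    } else {
      m <- apply_mask(mat, mask)
      list(matrix = filter_genes(m, config$matrix$min_total,
                                 config$matrix$min_fano), mask = mask)
    }
  })
  write_matrix_tsv(filtered$matrix, file.path(out_dir, "filtered_matrix.tsv"))

  cm <- run_stage("correlate", {
    al <- intersect_genes(profile, filtered$matrix)
    correlation_map(al$profile, al$matrix,
                    normalize = config$mapping$normalize)
  })
  corr_df <- data.frame(subtype = cm$subtype_ids, cm$r, check.names = FALSE,
                        row.names = NULL)
  names(corr_df) <- c("subtype", cm$voxel_ids)
  write_tsv(corr_df, file.path(out_dir, "correlation_map.tsv"))
  summary_df <- data.frame(
    subtype = cm$subtype_ids,
    max_r = apply(cm$r, 1, max, na.rm = TRUE),
    peak_voxel = cm$voxel_ids[apply(cm$r, 1, which.max)])
  write_tsv(summary_df, file.path(out_dir, "subtype_summary.tsv"))

  density_maps <- NULL; pw <- NULL
  if (!is.null(cell_tables)) {
    density_maps <- run_stage("map-projections", {
      pops <- unique(cell_tables$population)
      lapply(stats::setNames(pops, pops), function(p)
        density_map(cell_tables, p, grid,
                    mirror_ml = isTRUE(config$density$mirror_ml)))
    })
    for (p in names(density_maps))
      write_tsv(data.frame(voxel = density_maps[[p]]$voxel_ids,
                           p = density_maps[[p]]$p),
                file.path(out_dir, sprintf("density_%s.tsv", p)))
    if (length(density_maps) >= 2) {
      pw <- run_stage("compare-maps", pairwise_map_correlation(
        density_maps,
        mask = if (isTRUE(config$density$mask_correlations))
          filtered$mask else NULL))
      write_tsv(data.frame(population = rownames(pw), pw,
                           check.names = FALSE),
                file.path(out_dir, "pairwise_density_correlation.tsv"))
    }
  }

  fish_summary <- NULL
  if (!is.null(fish_tables) && !is.null(fish_plan)) {
    fish_summary <- run_stage("quantify-fish",
      summarize_panel(fish_tables, fish_plan,
                      min_puncta = config$fish$min_puncta))
    write_tsv(fish_summary, file.path(out_dir, "fish_summary.tsv"))
  }

  cfg_path <- write_config(config, file.path(out_dir, "config.yaml"))
  prov <- list(
    package = "raphemap",
    version = as.character(utils::packageVersion("raphemap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_md5 = unname(tools::md5sum(cfg_path)),
    input_md5 = if (is.character(manifest))
      as.list(tools::md5sum(manifest)) else NULL,
    n_genes_in = nrow(mat$values),
    n_genes_surviving = nrow(filtered$matrix$values),
    n_voxels_masked = ncol(filtered$matrix$values),
    n_shared_genes = length(intersect(profile$gene_ids,
                                      filtered$matrix$gene_ids))
  )
  atomic_write(file.path(out_dir, "provenance.json"), function(tmp)
    jsonlite::write_json(prov, tmp, auto_unbox = TRUE, pretty = TRUE))

  message(sprintf(
    "pipeline complete: %d genes -> %d surviving, %d masked voxels, %d subtype maps",
    prov$n_genes_in, prov$n_genes_surviving, prov$n_voxels_masked,
    nrow(cm$r)))
  invisible(list(matrix = mat, filtered = filtered$matrix,
                 mask = filtered$mask, corr_map = cm,
                 density_maps = density_maps, pairwise = pw,
                 fish_summary = fish_summary, audit = proc$audit,
                 out_dir = out_dir))
}

#' Run the planted-truth synthetic benchmark end to end
#'
#' Generates the standard synthetic study (5 subtype domains, 120 genes =
#' 20 enriched per subtype + 20 shared background genes, ISH images at
#' 10 um/px with 6 um cell blobs, cluster profiles at 10% multiplicative
#' noise), runs the full imaging-to-correlation pipeline on it, and scores
#' argmax-subtype recovery inside the planted domains.
#'
#' The pipeline configuration for this run keeps every default except:
#' no further downsampling (images are generated at working resolution),
#' a crop spanning the full 1.8 mm grid width (the synthetic tissue fills
#' the grid), and the first background gene as the marker-mask gene (it is
#' expressed across every domain, playing the Tph2 role).
#'
#' @param seed Integer master seed for the whole benchmark.
#' @param dir Directory for the rendered dataset (created; ~35 MB).
#' @param n_subtypes,n_genes Ground-truth dimensions.
#' @param noise_cv Cluster-profile noise level.
#' @param cells_per_unit Image cell-density scale.
#' @return List with `truth`, `result` (the [run_pipeline()] output),
#'   `recovery` (the [evaluate_recovery()] score) and `config`.
#' @export
run_synthetic_benchmark <- function(seed = 1,
                                    dir = tempfile("raphemap_bench"),
                                    n_subtypes = 5, n_genes = 120,
                                    noise_cv = 0.1, cells_per_unit = 400) {
  truth <- generate_ground_truth(n_subtypes, n_genes, seed = seed)
  ds <- synthetic_ish_dataset(truth, dir, cells_per_unit = cells_per_unit,
                              seed = seed + 1)
  prof <- simulate_cluster_profiles(truth, noise_cv = noise_cv,
                                    seed = seed + 2)
  bg <- setdiff(rownames(truth$gene_loadings),
                unique(unlist(truth$enriched_genes)))
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$ish$downsample_factor <- 1L
  cfg$ish$crop_width_um <- truth$grid$n_ml * truth$grid$bin_size_um
  cfg$matrix$marker_gene <- if (length(bg) > 0) bg[1] else
    rownames(truth$gene_loadings)[1]
  res <- run_pipeline(ds$manifest, prof, cfg,
                      out_dir = file.path(dir, "run"))
  list(truth = truth, result = res,
       recovery = evaluate_recovery(res$corr_map, truth), config = cfg)
}
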