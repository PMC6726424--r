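#' Generate a planted ground truth for the synthetic pipeline
#'
#' Builds a known answer that every downstream stage can be validated
#' against: spatially compact subtype domains on the analysis grid, and a
#' gene-loading matrix in which each subtype owns a block of enriched
#' marker genes over a shared background.
#'
#' Each subtype's domain is a 2D Gaussian per section whose (ML, DV)
#' center drifts linearly along AP, weighted by a Gaussian AP envelope, so
#' domains segregate along all three anatomical axes. Densities are
#' symmetrized about the ML midline (bilateral domains), consistent with
#' the reflection-averaging applied to every histogram downstream, and
#' each is normalized to sum to 1 over the voxels.
#'
#' Genes are split into `n_subtypes` blocks of `n_enriched_per_subtype`
#' subtype-enriched genes (loading ratio >= 4x over every other subtype by
#' construction) followed by shared background genes with equal loading
#' across subtypes. `enriched_genes` is derived from the loadings by the
#' ratio rule, so with a single subtype every gene is (vacuously) enriched.
#'
#' @param n_subtypes Number of subtypes (>= 1).
#' @param n_genes Number of genes (>= `n_subtypes`).
#' @param grid A [grid_spec()].
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param n_enriched_per_subtype Enriched genes per subtype; default
#'   `max(1, floor(n_genes / (n_subtypes + 1)))`, leaving roughly one
#'   block's worth of background genes.
#' @param domain_sigma_um In-plane Gaussian SD of each domain, um.
#' @param ap_sigma_sections Gaussian SD of the AP envelope, in sections.
#' @param enriched_loading,off_loading,background_loading Mean expression
#'   loading of an enriched gene in its own subtype, in other subtypes,
#'   and of background genes (arbitrary units).
#' @return An object of class `ground_truth` with fields `grid`,
#'   `n_subtypes`, `subtype_ids`, `domain_density` (voxels x subtypes,
#'   columns sum to 1), `gene_loadings` (genes x subtypes),
#'   `enriched_genes` (list per subtype), `centers`, `seed`.
#' @export
generate_ground_truth <- function(n_subtypes, n_genes, grid = grid_spec(),
                                  seed = 1,
                                  n_enriched_per_subtype = NULL,
                                  domain_sigma_um = 150,
                                  ap_sigma_sections = 1.5,
                                  enriched_loading = 5,
                                  off_loading = 0.5,
                                  background_loading = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  if (n_subtypes < 1) stop("n_subtypes must be >= 1", call. = FALSE)
  if (n_genes < n_subtypes)
    stop("n_genes must be >= n_subtypes", call. = FALSE)
  S <- as.integer(n_subtypes)
  if (is.null(n_enriched_per_subtype))
    n_enriched_per_subtype <- max(1L, floor(n_genes / (S + 1)))
  n_en <- as.integer(n_enriched_per_subtype)
  if (n_en * S > n_genes)
    stop("n_enriched_per_subtype * n_subtypes exceeds n_genes", call. = FALSE)

  bin <- grid$bin_size_um
  width_um <- grid$n_ml * bin
  height_um <- grid$n_dv * bin
  half_ml <- width_um / 2

  withr::with_seed(as.integer(seed), {
    frac <- (seq_len(S) - 0.5) / S
    dfrac <- ((seq_len(S) - 1) * 0.6180339887) %% 1
    centers <- data.frame(
      subtype = sprintf("sub%d", seq_len(S)),
      ml_um = half_ml + frac * 0.6 * half_ml + stats::runif(S, -0.4, 0.4) * bin,
      dv_um = (0.2 + 0.6 * dfrac) * height_um + stats::runif(S, -0.4, 0.4) * bin,
      ap_center = 1 + frac * (grid$n_sections - 1),
      dv_drift_um = (frac - 0.5) * 2 * bin,  # per section
      stringsAsFactors = FALSE
    )

    vt <- voxel_index_table(grid)
    ml <- (vt$col - 0.5) * bin
    dv <- (vt$row - 0.5) * bin
    dens <- matrix(0, nrow(vt), S,
                   dimnames = list(NULL, centers$subtype))
    flip <- match(
      sprintf("s%d_r%d_c%d", vt$section - 1L, vt$row - 1L, grid$n_ml - vt$col),
      vt$id)
    for (s in seq_len(S)) {
      dvc <- centers$dv_um[s] +
        centers$dv_drift_um[s] * (vt$section - centers$ap_center[s])
      d <- exp(-((ml - centers$ml_um[s])^2 + (dv - dvc)^2) /
                 (2 * domain_sigma_um^2)) *
        exp(-(vt$section - centers$ap_center[s])^2 / (2 * ap_sigma_sections^2))
      d <- (d + d[flip]) / 2               # bilateral (ML-symmetric) domain
      dens[, s] <- d / sum(d)
    }

    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    load <- matrix(0, n_genes, S, dimnames = list(gene_ids, centers$subtype))
    owner <- rep(NA_integer_, n_genes)
    if (n_en > 0)
      owner[seq_len(n_en * S)] <- rep(seq_len(S), each = n_en)
    for (g in seq_len(n_genes)) {
      if (!is.na(owner[g])) {
        load[g, ] <- off_loading * stats::runif(S, 0.8, 1.2)
        load[g, owner[g]] <- enriched_loading * stats::runif(1, 0.8, 1.2)
      } else {
        load[g, ] <- background_loading * stats::runif(1, 0.8, 1.2)
      }
    }

    enriched <- lapply(seq_len(S), function(s) {
      if (S == 1) return(gene_ids)
      other_max <- apply(load[, -s, drop = FALSE], 1, max)
      gene_ids[load[, s] >= 4 * other_max]
    })
    names(enriched) <- centers$subtype

    structure(list(
      grid = grid, n_subtypes = S, subtype_ids = centers$subtype,
      domain_density = dens, gene_loadings = load,
      enriched_genes = enriched, centers = centers, seed = as.integer(seed)
    ), class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d subtypes, %d genes on %d voxels (seed %d)\n",
              x$n_subtypes, nrow(x$gene_loadings),
              nrow(x$domain_density), x$seed))
  invisible(x)
}

# voxel rows of `truth$domain_density` belonging to one section
section_voxels <- function(grid, section) {
  npersec <- grid$n_ml * grid$n_dv
  (section - 1L) * npersec + seq_len(npersec)
}

render_gaussian_spots <- function(nx, ny, px_size_um, x_um, y_um, sigma_um,
                                  amplitude = 1) {
  img <- matrix(0, ny, nx)
  if (length(x_um) == 0) return(img)
  r <- max(1L, ceiling(3 * sigma_um / px_size_um))
  for (i in seq_along(x_um)) {
    cj <- x_um[i] / px_size_um + 0.5     # fractional pixel column
    ci <- y_um[i] / px_size_um + 0.5
    js <- max(1L, floor(cj - r)):min(nx, ceiling(cj + r))
    is <- max(1L, floor(ci - r)):min(ny, ceiling(ci + r))
    if (length(js) == 0 || length(is) == 0) next
    gx <- exp(-(((js - 0.5) * px_size_um - x_um[i])^2) / (2 * sigma_um^2))
    gy <- exp(-(((is - 0.5) * px_size_um - y_um[i])^2) / (2 * sigma_um^2))
    img[is, js] <- img[is, js] + amplitude * outer(gy, gx)
  }
  img
}

#' Simulate an ISH-like image for one gene and section
#'
#' Draws cell positions from the mixture of subtype domains weighted by the
#' gene's loadings, restricted to the section, and renders each cell as a
#' 2D Gaussian intensity blob on a grayscale image covering the grid's
#' in-plane extent. Additive Gaussian background noise is applied and the
#' image is clipped to the normalized intensity range [0, 1].
#'
#' The expected number of cells is `cells_per_unit` times the total mixture
#' weight in the section (Poisson distributed), so doubling
#' `cells_per_unit` doubles the expected planted count.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param gene Gene id present in the truth.
#' @param section AP section index.
#' @param cells_per_unit Density scale (expected cells per unit of summed
#'   loading-weighted domain mass).
#' @param px_size_um Pixel size, um.
#' @param blob_sigma_um Rendered cell-body Gaussian SD, um.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param seed Integer seed.
#' @return A list of class `sim_ish`: `image` (matrix, rows = DV pixels),
#'   `cells` (data.frame of planted `x_um`, `y_um`), `gene`, `section`,
#'   `px_size_um`.
#' @export
simulate_ish_image <- function(truth, gene, section, cells_per_unit = 400,
                               px_size_um = 10, blob_sigma_um = 6,
                               noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  grid <- truth$grid
  if (!gene %in% rownames(truth$gene_loadings))
    stop(sprintf("unknown gene '%s'", gene), call. = FALSE)
  if (!(section %in% seq_len(grid$n_sections)))
    stop(sprintf("section %s outside grid", section), call. = FALSE)
  bin <- grid$bin_size_um
  nx <- round(grid$n_ml * bin / px_size_um)
  ny <- round(grid$n_dv * bin / px_size_um)
  idx <- section_voxels(grid, section)
  w <- as.vector(truth$domain_density[idx, , drop = FALSE] %*%
                   truth$gene_loadings[gene, ])

  withr::with_seed(as.integer(seed), {
    n <- if (sum(w) > 0) stats::rpois(1, cells_per_unit * sum(w)) else 0L
    if (n > 0) {
      v <- sample.int(length(w), n, replace = TRUE, prob = w)
      col <- (v - 1L) %% grid$n_ml
      row <- (v - 1L) %/% grid$n_ml
      cells <- data.frame(x_um = (col + stats::runif(n)) * bin,
                          y_um = (row + stats::runif(n)) * bin)
    } else {
      cells <- data.frame(x_um = numeric(0), y_um = numeric(0))
    }
    img <- render_gaussian_spots(nx, ny, px_size_um,
                                 cells$x_um, cells$y_um, blob_sigma_um)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), ny, nx)
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, cells = cells, gene = gene,
                   section = as.integer(section), px_size_um = px_size_um),
              class = "sim_ish")
  })
}

#' Cluster-averaged expression profile container
#'
#' @param values Nonnegative genes x subtypes matrix with row and column
#'   names.
#' @return An object of class `cluster_profile`.
#' @export
cluster_profile <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("profile rows must carry unique gene ids", call. = FALSE)
  if (any(colSums(is.finite(values)) == 0))
    stop("profile contains an all-missing subtype column", call. = FALSE)
  structure(list(values = values, gene_ids = rownames(values),
                 subtype_ids = colnames(values)),
            class = "cluster_profile")
}

#' Simulate noisy cluster-averaged subtype profiles
#'
#' Perturbs the ground-truth gene loadings with multiplicative lognormal
#' noise of unit mean and coefficient of variation `noise_cv`, emulating
#' cluster-averaged single-cell expression estimates. `noise_cv = 0`
#' returns the loadings exactly.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return A [cluster_profile()].
#' @export
simulate_cluster_profiles <- function(truth, noise_cv = 0.1, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  vals <- truth$gene_loadings
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    vals <- withr::with_seed(as.integer(seed), {
      vals * matrix(stats::rlnorm(length(vals), -sdlog^2 / 2, sdlog),
                    nrow(vals), ncol(vals))
    })
  }
  cluster_profile(vals)
}

# sample voxel indices from a density over the grid and jitter uniformly
# within each voxel; returns x_um, y_um, ap_section
sample_cells_from_density <- function(grid, dens, n) {
  if (n == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      ap_section = integer(0)))
  v <- sample.int(length(dens), n, replace = TRUE, prob = dens)
  npersec <- grid$n_ml * grid$n_dv
  sec <- (v - 1L) %/% npersec + 1L
  rem <- (v - 1L) %% npersec
  row <- rem %/% grid$n_ml
  col <- rem %% grid$n_ml
  data.frame(x_um = (col + stats::runif(n)) * grid$bin_size_um,
             y_um = (row + stats::runif(n)) * grid$bin_size_um,
             ap_section = sec)
}

#' Simulate registered labeled-cell coordinates
#'
#' Emulates a retrogradely labeled neuron population registered onto the
#' coronal template: cell positions are sampled from the mixture of
#' subtype domains with the given weights and jittered uniformly within
#' voxels.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param mixture Nonnegative per-subtype weights (sum > 0).
#' @param n_cells Number of cells to sample.
#' @param seed Integer seed.
#' @param population,animal Labels attached to every row.
#' @return A data.frame with columns `x_um`, `y_um`, `ap_section`,
#'   `population`, `animal`.
#' @export
simulate_projection_cells <- function(truth, mixture, n_cells, seed = 1,
                                      population = "pop1", animal = "a1") {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(mixture) != truth$n_subtypes)
    stop("mixture must have one weight per subtype", call. = FALSE)
  if (any(mixture < 0) || sum(mixture) <= 0)
    stop("mixture weights must be nonnegative with positive sum",
         call. = FALSE)
  dens <- as.vector(truth$domain_density %*% mixture)
  withr::with_seed(as.integer(seed), {
    cells <- sample_cells_from_density(truth$grid, dens, n_cells)
    cells$population <- rep(population, nrow(cells))
    cells$animal <- rep(animal, nrow(cells))
    cells
  })
}

#' Simulate a per-cell FISH puncta-count table
#'
#' Cells are assigned a subtype (uniformly) and a location sampled from
#' that subtype's domain. For each probe, puncta counts are Poisson with
#' mean `lambda_pos` when the probe is enriched in the cell's subtype and
#' `lambda_neg` otherwise, making threshold-based positivity calling
#' analytically checkable against Poisson tail probabilities.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param probes Gene ids to measure (must exist in the truth).
#' @param n_cells Number of cells.
#' @param lambda_pos,lambda_neg Mean puncta for enriched / non-enriched
#'   probe-subtype pairs (`lambda_pos > lambda_neg >= 0`).
#' @param seed Integer seed.
#' @return A data.frame with columns `cell_id`, `x_um`, `y_um`,
#'   `ap_section`, `subtype`, then one integer puncta column per probe.
#' @export
simulate_fish_table <- function(truth, probes, n_cells,
                                lambda_pos = 20, lambda_neg = 0.2, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  unknown <- setdiff(probes, rownames(truth$gene_loadings))
  if (length(unknown) > 0)
    stop(sprintf("unknown probe(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (!(lambda_pos > lambda_neg && lambda_neg >= 0))
    stop("need lambda_pos > lambda_neg >= 0", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    s <- sample.int(truth$n_subtypes, n_cells, replace = TRUE)
    cells <- data.frame(x_um = numeric(n_cells), y_um = numeric(n_cells),
                        ap_section = integer(n_cells))
    for (si in unique(s)) {             # bulk-sample per subtype
      pick <- which(s == si)
      cells[pick, ] <- sample_cells_from_density(
        truth$grid, truth$domain_density[, si], length(pick))
    }
    tab <- data.frame(cell_id = sprintf("c%05d", seq_len(n_cells)),
                      cells[, c("x_um", "y_um", "ap_section")],
                      subtype = truth$subtype_ids[s][seq_len(n_cells)],
                      stringsAsFactors = FALSE)
    for (p in probes) {
      enr <- vapply(s, function(si) p %in% truth$enriched_genes[[si]],
                    logical(1))
      lam <- ifelse(enr, lambda_pos, lambda_neg)
      tab[[p]] <- if (n_cells > 0) stats::rpois(n_cells, lam) else integer(0)
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Write a complete synthetic ISH dataset to disk
#'
#' Renders one ISH-like TIFF per gene x section from the planted truth
#' and writes the manifest linking images to AP position and pixel size,
#' in the exact on-disk layout the imaging pipeline consumes. Per-image
#' seeds are derived deterministically from `seed`.
#'
#' @param truth A [generate_ground_truth()] object.
#' @param dir Output directory (created).
#' @param cells_per_unit,px_size_um,blob_sigma_um,noise_sd Passed to
#'   [simulate_ish_image()].
#' @param seed Integer master seed.
#' @return List with `manifest` (path to the manifest TSV) and `planted`
#'   (data.frame of every planted cell: gene, section, x_um, y_um).
#' @export
synthetic_ish_dataset <- function(truth, dir, cells_per_unit = 400,
                                  px_size_um = 10, blob_sigma_um = 6,
                                  noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  grid <- truth$grid
  genes <- rownames(truth$gene_loadings)
  rows <- list(); planted <- list(); k <- 0L
  for (g in genes) for (sec in seq_len(grid$n_sections)) {
    k <- k + 1L
    sk <- (as.integer(seed) %% 100000L) * 20011L + k
    sim <- simulate_ish_image(truth, g, sec, cells_per_unit = cells_per_unit,
                              px_size_um = px_size_um,
                              blob_sigma_um = blob_sigma_um,
                              noise_sd = noise_sd, seed = sk)
    path <- file.path(dir, "images", sprintf("%s_s%02d.tif", g, sec))
    write_image(sim$image, path)
    rows[[k]] <- data.frame(
      gene = g, ap_mm = (sec - 1) * grid$ap_interval_um / 1000,
      px_size_um = px_size_um, path = path, replicate = 1L,
      stringsAsFactors = FALSE)
    if (nrow(sim$cells) > 0)
      planted[[k]] <- data.frame(gene = g, section = sec, sim$cells)
  }
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(do.call(rbind, rows), manifest_path)
  list(manifest = manifest_path,
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(gene = character(0), section = integer(0),
                    x_um = numeric(0), y_um = numeric(0)))
}

#' Voxels inside a subtype's planted domain
#'
#' The planted domain of a subtype is defined as the voxels whose density
#' is at least `level` times the subtype's peak density (half-maximum
#' support by default).
#'
#' @param truth A [generate_ground_truth()] object.
#' @param subtype Subtype index or id.
#' @param level Fraction of the peak density (default 0.5).
#' @return Integer voxel indices.
#' @export
domain_voxels <- function(truth, subtype, level = 0.5) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.character(subtype)) subtype <- match(subtype, truth$subtype_ids)
  d <- truth$domain_density[, subtype]
  which(d >= level * max(d))
}

#' Score argmax-subtype recovery against the planted truth
#'
#' For every voxel inside a planted domain (half-maximum support) that is
#' present in the correlation map, checks whether the subtype with the
#' highest correlation is the planted one.
#'
#' @param cm A [correlation_map()] whose subtype order matches the truth.
#' @param truth The [generate_ground_truth()] object.
#' @param level Domain support level (see [domain_voxels()]).
#' @return List with `accuracy`, `n_evaluated`, `n_in_domain`, and
#'   `per_subtype` (data.frame).
#' @export
evaluate_recovery <- function(cm, truth, level = 0.5) {
  stopifnot(inherits(cm, "correlation_map"), inherits(truth, "ground_truth"))
  vt <- voxel_index_table(truth$grid)
  per <- lapply(seq_len(truth$n_subtypes), function(s) {
    dom <- domain_voxels(truth, s, level)
    pos <- match(vt$id[dom], cm$voxel_ids)
    pos <- pos[!is.na(pos)]
    hit <- if (length(pos) > 0) {
      vapply(pos, function(v) {
        r <- cm$r[, v]
        is.finite(max(r)) && which.max(r) == s
      }, logical(1))
    } else logical(0)
    data.frame(subtype = truth$subtype_ids[s], n_in_domain = length(dom),
               n_evaluated = length(pos), n_correct = sum(hit))
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(per$n_correct) / max(1, sum(per$n_evaluated)),
       n_evaluated = sum(per$n_evaluated),
       n_in_domain = sum(per$n_in_domain),
       per_subtype = per)
}
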