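#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Plants the ground truth used by every later stage: 5 bilateral subtype
# domains on the 36 x 36 x 12 voxel grid (50 um bins, 100 um AP steps),
# 120 genes (20 enriched per subtype at >= 4x loading ratio + 20 shared
# background genes), then renders one ISH-like TIFF per gene x section at
# 10 um/px and writes the cluster-averaged expression profile (10%
# multiplicative noise), projection-labeled cell tables and a FISH puncta
# table. Images land under scratch/ (bulky, regenerable); tables and the
# manifest under scratch/synthetic as pipeline inputs.

library(raphemap)

seed <- 1L
dir <- "scratch/synthetic"
dir.create(dir, recursive = TRUE, showWarnings = FALSE)

truth <- generate_ground_truth(5, 120, seed = seed)
print(truth)

message("rendering ISH images (1440 sections)...")
ds <- synthetic_ish_dataset(truth, dir, seed = seed + 1)
message(sprintf("planted %d cells across %d images",
                nrow(ds$planted), 120 * 12))

profile <- simulate_cluster_profiles(truth, noise_cv = 0.1, seed = seed + 2)
write_profile(profile, file.path(dir, "cluster_profile.tsv"))

# two projection-defined populations: one concentrated in subtype 2's
# domain, one split between subtypes 4 and 5 (overlapping targets)
cells <- rbind(
  simulate_projection_cells(truth, c(0, 1, 0, 0, 0), 1500, seed = seed + 3,
                            population = "popA", animal = "a1"),
  simulate_projection_cells(truth, c(0, 0, 0, 1, 1), 1500, seed = seed + 4,
                            population = "popB", animal = "a2"))
write_tsv(cells, file.path(dir, "projection_cells.tsv"))

# FISH: one probe per subtype measured on cells drawn from all domains
probes <- vapply(truth$enriched_genes, `[`, character(1), 1)
fish <- simulate_fish_table(truth, probes, n_cells = 800,
                            lambda_pos = 20, lambda_neg = 0.2,
                            seed = seed + 5)
write_tsv(fish, file.path(dir, "fish_table.tsv"))

# pipeline configuration for this study: images are already at working
# resolution (no further downsampling), the crop spans the full grid, and
# the first background gene stands in for Tph2 as the mask marker
bg <- setdiff(rownames(truth$gene_loadings),
              unique(unlist(truth$enriched_genes)))
cfg <- default_config()
cfg$seed <- seed
cfg$ish$downsample_factor <- 1L
cfg$ish$crop_width_um <- 1800
cfg$matrix$marker_gene <- bg[1]
write_config(cfg, file.path(dir, "config.yaml"))

message(sprintf("study written under %s (marker gene %s)", dir, bg[1]))
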