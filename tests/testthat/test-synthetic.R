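test_that("ground truth satisfies its structural invariants", {
  truth <- generate_ground_truth(5, 100, grid_spec(), seed = 7)
  expect_equal(unname(colSums(truth$domain_density)), rep(1, 5),
               tolerance = 1e-9)
  expect_true(all(truth$domain_density >= 0))
  # every subtype has at least one gene enriched >= 4x over all others
  for (s in seq_len(5)) {
    expect_gt(length(truth$enriched_genes[[s]]), 0)
    g <- truth$enriched_genes[[s]][1]
    expect_gte(truth$gene_loadings[g, s],
               4 * max(truth$gene_loadings[g, -s]))
  }
  # pairwise distinct centers
  d <- as.matrix(dist(truth$centers[, c("ml_um", "dv_um", "ap_center")]))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("ground truth is deterministic under a fixed seed and validates input", {
  t1 <- generate_ground_truth(3, 20, small_grid(), seed = 7)
  t2 <- generate_ground_truth(3, 20, small_grid(), seed = 7)
  expect_identical(t1, t2)
  t3 <- generate_ground_truth(3, 20, small_grid(), seed = 8)
  expect_false(identical(t1$gene_loadings, t3$gene_loadings))
  expect_error(generate_ground_truth(5, 3, small_grid()), "n_genes")
})

test_that("single-subtype truth has one unit-mass domain and all genes enriched", {
  truth <- generate_ground_truth(1, 5, small_grid(), seed = 0)
  expect_equal(ncol(truth$domain_density), 1)
  expect_equal(sum(truth$domain_density), 1, tolerance = 1e-9)
  expect_setequal(truth$enriched_genes[[1]], rownames(truth$gene_loadings))
})

test_that("ISH simulation plants cells from the loading-weighted mixture", {
  truth <- small_truth(2, 6, seed = 3)
  # zero-loading gene -> pure background noise, no planted cells
  truth0 <- truth
  truth0$gene_loadings["g001", ] <- 0
  sim <- simulate_ish_image(truth0, "g001", 1, noise_sd = 0.05, seed = 4)
  expect_equal(nrow(sim$cells), 0)
  expect_true(max(sim$image) < 0.4)   # noise only (sd 0.05, clipped)
  # determinism
  s1 <- simulate_ish_image(truth, "g002", 2, seed = 9)
  s2 <- simulate_ish_image(truth, "g002", 2, seed = 9)
  expect_identical(s1, s2)
  # unknown gene / section
  expect_error(simulate_ish_image(truth, "nope", 1), "unknown gene")
  expect_error(simulate_ish_image(truth, "g001", 99), "section")
})

test_that("expected planted-cell count scales linearly with cells_per_unit", {
  truth <- small_truth(2, 6, seed = 3)
  n1 <- vapply(1:150, function(k)
    nrow(simulate_ish_image(truth, "g001", 1, cells_per_unit = 100,
                            noise_sd = 0, seed = k)$cells), numeric(1))
  n2 <- vapply(1:150, function(k)
    nrow(simulate_ish_image(truth, "g001", 1, cells_per_unit = 200,
                            noise_sd = 0, seed = 1000 + k)$cells), numeric(1))
  # Poisson means: ratio within 4 SE of 2
  se <- sqrt(var(n2) / length(n2)) / mean(n1) +
    mean(n2) * sqrt(var(n1) / length(n1)) / mean(n1)^2
  expect_lt(abs(mean(n2) / mean(n1) - 2), 4 * se)
})

test_that("a noise-free single planted cell puts the image maximum at its location", {
  truth <- small_truth(1, 2, seed = 1)
  n <- 0; k <- 0
  while (n != 1) {                      # first seed yielding exactly 1 cell
    k <- k + 1
    sim <- simulate_ish_image(truth, "g001", 1, cells_per_unit = 1,
                              noise_sd = 0, seed = k)
    n <- nrow(sim$cells)
  }
  peak <- which(sim$image == max(sim$image), arr.ind = TRUE)[1, ]
  expect_lt(abs((peak["col"] - 0.5) * 10 - sim$cells$x_um[1]), 10)
  expect_lt(abs((peak["row"] - 0.5) * 10 - sim$cells$y_um[1]), 10)
})

test_that("cluster profiles carry calibrated multiplicative noise", {
  truth <- generate_ground_truth(4, 1000, small_grid(), seed = 2)
  p0 <- simulate_cluster_profiles(truth, noise_cv = 0, seed = 1)
  expect_identical(p0$values, truth$gene_loadings)
  p1 <- simulate_cluster_profiles(truth, noise_cv = 0.1, seed = 1)
  expect_identical(p1$values,
                   simulate_cluster_profiles(truth, 0.1, seed = 1)$values)
  expect_true(all(p1$values >= 0))
  ratio <- p1$values / truth$gene_loadings
  expect_lt(abs(sd(ratio) / mean(ratio) - 0.1), 0.01)
  expect_error(simulate_cluster_profiles(truth, -1), "noise_cv")
})

test_that("projection cells reproduce the planted density", {
  truth <- small_truth(2, 6, seed = 3)
  cells <- simulate_projection_cells(truth, c(1, 0), 1e5, seed = 6)
  pm <- density_map(cells, "pop1", truth$grid)
  tv <- 0.5 * sum(abs(pm$p - truth$domain_density[, 1]))
  expect_lt(tv, 0.05)
  # empty request and argument validation
  empty <- simulate_projection_cells(truth, c(1, 1), 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_projection_cells(truth, c(0, 0), 10), "weights")
  expect_error(simulate_projection_cells(truth, c(1, 1, 1), 10), "per subtype")
})

test_that("an equal two-domain mixture splits cells evenly between supports", {
  truth <- small_truth(2, 6, seed = 3)
  cells <- simulate_projection_cells(truth, c(1, 1), 4000, seed = 8)
  vt <- voxel_index_table(truth$grid)
  b <- truth$grid$bin_size_um
  vox <- match(sprintf("s%d_r%d_c%d",
                       cells$ap_section - 1L,
                       pmin(floor(cells$y_um / b), truth$grid$n_dv - 1),
                       pmin(floor(cells$x_um / b), truth$grid$n_ml - 1)),
               vt$id)
  frac1 <- mean(truth$domain_density[vox, 1] > truth$domain_density[vox, 2])
  expect_lt(abs(frac1 - 0.5), 4 * sqrt(0.25 / 4000))
})

test_that("FISH tables follow the enrichment-conditional Poisson model", {
  truth <- small_truth(3, 9, seed = 2)
  probes <- vapply(truth$enriched_genes, `[`, character(1), 1)
  tab <- simulate_fish_table(truth, probes, 500, lambda_pos = 10,
                             lambda_neg = 0, seed = 3)
  expect_equal(nrow(tab), 500)
  for (s in seq_len(3)) {
    other <- tab$subtype != truth$subtype_ids[s]
    expect_true(all(tab[[probes[s]]][other] == 0))  # Poisson(0)
  }
  expect_identical(tab, simulate_fish_table(truth, probes, 500, 10, 0,
                                            seed = 3))
  expect_error(simulate_fish_table(truth, "nope", 10), "unknown probe")
  expect_error(simulate_fish_table(truth, probes, 10, 1, 2), "lambda")
})

test_that("the on-disk synthetic dataset round-trips through the manifest", {
  truth <- small_truth(2, 3, seed = 4)
  dir <- withr::local_tempdir()
  ds <- synthetic_ish_dataset(truth, dir, seed = 4)
  man <- read_manifest(ds$manifest)
  expect_equal(nrow(man), 3 * truth$grid$n_sections)
  expect_true(all(file.exists(man$path)))
  img <- read_image(man$path[1])
  expect_equal(dim(img), c(60, 60))   # 600 um at 10 um/px
})
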