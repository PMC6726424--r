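test_that("gene intersection harmonizes both inputs", {
  g <- small_grid()
  mk <- function(genes) {
    v <- matrix(runif(length(genes) * n_voxels(g)), length(genes))
    rownames(v) <- genes
    m <- build_matrix(stats::setNames(
      lapply(seq_along(genes), function(i) v[i, ]), genes), g)
    m
  }
  prof <- cluster_profile(matrix(runif(6), 3, 2,
                                 dimnames = list(c("A", "B", "C"),
                                                 c("s1", "s2"))))
  m <- mk(c("B", "C", "D"))
  suppressMessages(al <- intersect_genes(prof, m))
  expect_identical(al$profile$gene_ids, c("B", "C"))
  expect_identical(al$matrix$gene_ids, c("B", "C"))
  suppressMessages(al2 <- intersect_genes(prof, mk(c("C", "A", "B"))))
  expect_identical(al2$profile$gene_ids, c("A", "B", "C"))
  expect_error(suppressMessages(intersect_genes(prof, mk(c("X", "Y")))),
               "no shared genes")
})

test_that("row z-scoring standardizes finite entries", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, 3))
  expect_equal(z, matrix(c(-1, 0, 1), 1, 3))
  expect_equal(zscore_rows(matrix(5, 1, 4)), matrix(0, 1, 4))
  expect_true(all(is.na(zscore_rows(matrix(5, 1, 4), "nan"))))
  set.seed(5)
  m <- matrix(rnorm(200, 3, 2), 4)
  zz <- zscore_rows(m)
  expect_equal(rowMeans(zz), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(zz, 1, sd), rep(1, 4), tolerance = 1e-12)
})

test_that("pearson matches the explicit sum formula and handles degeneracies", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  # independent oracle: raw sum formula
  n <- 3
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(pearson(x, y), num / den, tolerance = 1e-14)
  expect_equal(pearson(x, y), 0.9934, tolerance = 1e-4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_true(is.na(pearson(c(1, 2, NA), c(1, NA, 3))))   # < 3 pairs
  expect_true(is.na(pearson(c(1, 1, 1), y)))              # constant
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("pearson agrees with the pairwise-complete reference on random data", {
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(40); y <- rnorm(40)
    x[sample(40, 5)] <- NA; y[sample(40, 5)] <- NA
    expect_lt(abs(pearson(x, y) -
                    cor(x, y, use = "pairwise.complete.obs")), 1e-10)
  }
})

test_that("correlation maps reproduce exact matches and scale invariance", {
  g <- grid_spec(n_ml = 2, n_dv = 1, n_sections = 2)   # 4 voxels
  pv <- matrix(c(1, 5, 2, 9, 4, 3, 7, 2), 4, 2,
               dimnames = list(sprintf("g%03d", 1:4), c("s1", "s2")))
  prof <- cluster_profile(pv)
  vals <- cbind(pv[, 1], 3 * pv[, 1], pv[, 2], runif(4))
  m <- matrix_from_values(vals, g)
  m$gene_ids <- rownames(pv); rownames(m$values) <- rownames(pv)
  cm <- correlation_map(prof, m, normalize = "raw")
  expect_equal(unname(cm$r["s1", 1]), 1)
  expect_equal(unname(cm$r["s1", 2]), 1)              # positive scaling
  expect_equal(unname(cm$r["s2", 3]), 1)
  expect_true(all(abs(cm$r[is.finite(cm$r)]) <= 1 + 1e-12))
  expect_equal(cm$n_genes_used, rep(4L, 4))
})

test_that("correlation maps equal a naive double-loop oracle", {
  g <- grid_spec(n_ml = 10, n_dv = 5, n_sections = 1)  # 50 voxels
  set.seed(23)
  P <- matrix(rlnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("g%03d", 1:20), c("a", "b", "c")))
  V <- matrix(rlnorm(20 * 50), 20, 50)
  V[sample(length(V), 30)] <- NA
  m <- matrix_from_values(V, g)
  cm <- correlation_map(cluster_profile(P), m, normalize = "zscore")
  Pz <- zscore_rows(P); Vz <- zscore_rows(V)
  for (s in 1:3) for (v in seq(1, 50, by = 3)) {
    expect_lt(abs(cm$r[s, v] -
                    cor(Pz[, s], Vz[, v], use = "pairwise.complete.obs")),
              1e-10)
  }
})

test_that("map reshaping restores the grid with NA at masked voxels", {
  g <- small_grid()
  set.seed(29)
  vals <- matrix(rpois(3 * n_voxels(g), 3) + 1, 3)
  m <- matrix_from_values(vals, g)
  mask <- build_marker_mask(m, "g001", 3)
  mm <- apply_mask(m, mask)
  P <- matrix(runif(9), 3, 3, dimnames = list(mm$gene_ids, c("x", "y", "z")))
  cm <- correlation_map(cluster_profile(P), mm)
  grids <- reshape_map(cm, "x")
  expect_length(grids, g$n_sections)
  flat <- section_to_grid_vector(grids, g)
  expect_equal(sum(is.finite(flat)), sum(is.finite(cm$r["x", ])))
  expect_true(all(is.na(flat[!voxel_index_table(g)$id %in% mm$voxel_ids])))
  expect_equal(flat[match(cm$voxel_ids, voxel_index_table(g)$id)],
               unname(cm$r["x", ]))
  expect_error(reshape_map(cm, "nope"), "unknown subtype")
})

test_that("symmetric spatial input yields ML-symmetric correlation maps", {
  g <- small_grid()
  set.seed(31)
  half <- matrix(rpois(4 * n_voxels(g), 2), 4)
  m0 <- matrix_from_values(half, g)
  # symmetrize each gene's per-section grids
  sym <- t(vapply(seq_len(4), function(i) {
    secs <- grid_vector_to_sections(half[i, ], g)
    section_to_grid_vector(lapply(secs, function(s) (s + s[, 12:1]) / 2), g)
  }, numeric(n_voxels(g))))
  m <- matrix_from_values(sym, g)
  P <- matrix(runif(8) + 0.5, 4, 2,
              dimnames = list(m$gene_ids, c("p", "q")))
  cm <- correlation_map(cluster_profile(P), m)
  for (s in c("p", "q")) {
    grids <- reshape_map(cm, s)
    for (gr in grids) expect_equal(gr, gr[, 12:1], tolerance = 1e-12)
  }
})

test_that("display rendering thresholds and smooths without moving peaks", {
  g <- lapply(1:2, function(i) matrix(0.05, 6, 6))
  out <- render_map(g, r_threshold = 0.1)
  expect_true(all(vapply(out, function(m) all(is.na(m)), logical(1))))
  m <- matrix(0, 6, 6); m[3, 4] <- 1
  r0 <- render_map(list(m), r_threshold = 0.1, smooth_sd_bins = 0)[[1]]
  expect_equal(which(!is.na(r0)), which(m > 0.1))
  r1 <- render_map(list(m), r_threshold = -1 + 1e-9, smooth_sd_bins = 1)[[1]]
  expect_equal(unname(which(r1 == max(r1, na.rm = TRUE), arr.ind = TRUE)[1, ]),
               c(3, 4))
  expect_error(render_map(list(m), r_threshold = 2), "r_threshold")
})
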