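test_that("block-mean downsampling matches its arithmetic contract", {
  img <- matrix(c(0, 4, 2, 6), 2, 2)     # [[0,2],[4,6]] row-wise
  expect_identical(downsample_image(img, 1), img)
  expect_equal(downsample_image(img, 2), matrix(3, 1, 1))
  expect_equal(downsample_image(matrix(7, 5, 5), 2), matrix(7, 2, 2))
  expect_error(downsample_image(img, 0), "factor")
})

test_that("midline estimation finds mirror axes, including shifted ones", {
  blob <- function(n, centers) {
    img <- matrix(0, 20, n)
    for (c0 in centers)
      img <- img + outer(dnorm(1:20, 10, 2), dnorm(seq_len(n), c0, 1.5))
    img
  }
  expect_equal(estimate_midline(blob(41, c(10, 30))), 20)
  # brute-force oracle over candidate half-integer axes
  img <- blob(41, c(8, 20, 32))          # symmetric about 20
  oracle <- function(img) {
    n <- ncol(img)
    best <- -Inf; arg <- NA
    for (c2 in 3:(2 * n - 1)) {          # axis = c2 / 2
      s <- 0
      for (j in seq_len(n)) {
        k <- c2 - j
        if (k >= 1 && k <= n) s <- s + sum(img[, j] * img[, k])
      }
      if (s > best) { best <- s; arg <- c2 / 2 }
    }
    arg
  }
  expect_equal(estimate_midline(img), oracle(img))
  # shifting a symmetric image moves the axis by the shift
  shifted <- cbind(matrix(0, 20, 6), img)[, 1:41]
  expect_equal(estimate_midline(shifted), 26)
  expect_error(estimate_midline(matrix(1, 5, 5)), "degenerate")
})

test_that("align_and_crop centers the window and zero-pads", {
  img <- matrix(runif(200), 10, 20)
  expect_equal(align_and_crop(img, 10.5, 200, 10), img)  # full width
  expect_equal(ncol(align_and_crop(img, 10, 1000, 10)), 100)
  out <- align_and_crop(img, 5, 1000, 10)               # 100-px window
  expect_true(all(out[, 1:45] == 0))
  expect_equal(out[, 46:55], img[, 1:10])
  expect_error(align_and_crop(img, 5, -1, 10), "width")
})

test_that("binarization thresholds by Otsu or a fixed value", {
  expect_warning(m <- binarize(matrix(0, 4, 4)), "constant")
  expect_false(any(m))
  expect_equal(binarize(matrix(c(50, 150), 1, 2), "fixed",
                        fixed_threshold = 100)[1, ],
               c(FALSE, TRUE))
  # bimodal image: Otsu threshold falls strictly between the modes;
  # oracle = exhaustive scan minimizing within-class variance
  set.seed(11)
  x <- pmin(pmax(c(rnorm(600, 30, 5), rnorm(400, 200, 10)), 0), 255)
  img <- matrix(x, 25, 40)
  mask <- binarize(img, "otsu")
  thr <- attr(mask, "threshold")
  expect_gt(thr, 30); expect_lt(thr, 200)
  wcv <- vapply(seq(1, 254), function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) < 2 || length(hi) < 2) return(Inf)
    length(lo) * var(lo) * (length(lo) - 1) / length(lo) +
      length(hi) * var(hi) * (length(hi) - 1) / length(hi)
  }, numeric(1))
  # any threshold in the inter-mode gap minimizes the objective; check
  # the returned threshold attains the optimum (within bin coarseness)
  expect_lte(wcv[round(thr)], min(wcv) * 1.001)
  expect_equal(as.vector(mask), as.vector(img > thr))
})

test_that("LoG detection recovers planted noise-free blobs exactly", {
  set.seed(21)
  pos <- planted_positions(25, 1000, 1000, min_sep_um = 4 * 6 * 2)
  img <- raphemap:::render_gaussian_spots(100, 100, 10, pos$x_um, pos$y_um, 6)
  sp <- detect_spots(img, sigma_um = 6, px_size_um = 10)
  m <- match_spots(sp, pos, radius_um = 10 * sqrt(2))  # within 1 px
  expect_equal(unname(m["tp"]), 25)
  expect_equal(unname(m["fp"]), 0)
  # blank image -> no spots
  expect_equal(nrow(detect_spots(matrix(0, 20, 20), 6, 10)), 0)
})

test_that("LoG detection is invariant to joint intensity/threshold scaling", {
  set.seed(22)
  pos <- planted_positions(5, 500, 500, 60)
  img <- raphemap:::render_gaussian_spots(50, 50, 10, pos$x_um, pos$y_um, 6)
  s1 <- detect_spots(img, 6, 10, min_response = 0.3)
  s2 <- detect_spots(img * 7, 6, 10, min_response = 0.3 * 7)
  expect_equal(s1$x_um, s2$x_um)
  expect_equal(s1$y_um, s2$y_um)
})

test_that("binning follows half-open lower-inclusive conventions and conserves counts", {
  g <- small_grid()
  sp <- spot_set(data.frame(x_um = c(50, 25, -10, 700),
                            y_um = c(50, 25, 30, 30)))
  h <- bin_spots(sp, g)
  expect_equal(h$counts[2, 2], 1)        # boundary spot -> higher bin
  expect_equal(h$counts[1, 1], 1)
  expect_equal(sum(h$counts) + h$dropped, 4)
  expect_equal(h$dropped, 2)
  # uniform spots fill bins multinomially
  set.seed(31)
  n <- 10000
  spu <- spot_set(data.frame(x_um = runif(n, 0, 600),
                             y_um = runif(n, 0, 600)))
  hu <- bin_spots(spu, g)
  expect_equal(sum(hu$counts), n)
  expect_gt(chisq.test(as.vector(hu$counts))$p.value, 0.001)
})

test_that("DV fine alignment recovers shifts and honors the manual override", {
  set.seed(41)
  base <- matrix(rpois(144, 2), 12, 12)
  base[4:6, ] <- base[4:6, ] + 20        # structured band
  h <- section_hist(base)
  ref_same <- section_hist(base)
  expect_equal(fine_align_dv(h, ref_same)$offset_dv, 0L)
  # reference shifted down 3 bins -> offset -3
  ref_down <- section_hist(raphemap:::shift_dv(base, -3))
  al <- fine_align_dv(h, ref_down, max_shift_bins = 5)
  expect_equal(al$offset_dv, -3L)
  expect_equal(al$counts[4:12, ], base[1:9, ])
  # brute-force oracle over all offsets
  best <- which.max(vapply(-5:5, function(o)
    cor(rowSums(raphemap:::shift_dv(base, o)), rowSums(ref_down$counts)),
    numeric(1)))
  expect_equal(al$offset_dv, (-5:5)[best])
  # manual override applies verbatim
  man <- fine_align_dv(h, ref_same, manual_offset = 2)
  expect_equal(man$offset_dv, 2L)
  expect_equal(man$counts, raphemap:::shift_dv(base, 2))
  expect_warning(z <- fine_align_dv(section_hist(matrix(0, 12, 12)),
                                    ref_same), "all-zero")
  expect_equal(z$offset_dv, 0L)
})

test_that("reflection averaging is exact, idempotent and count-preserving", {
  h <- section_hist(matrix(c(1, 3), 1, 2))
  expect_equal(reflect_average(h)$counts, matrix(2, 1, 2))
  set.seed(51)
  m <- matrix(rpois(144, 3), 12, 12)
  r1 <- reflect_average(section_hist(m))
  expect_identical(r1$counts, r1$counts[, 12:1])     # bitwise symmetry
  expect_equal(sum(r1$counts), sum(m))
  expect_identical(reflect_average(r1)$counts, r1$counts)
})

test_that("grid vectorization is invertible with documented index order", {
  g <- grid_spec()                        # full 36 x 36 x 12
  set.seed(61)
  mats <- lapply(1:12, function(i) matrix(rnorm(1296), 36, 36))
  v <- section_to_grid_vector(mats, g)
  expect_equal(length(v), 15552)
  back <- grid_vector_to_sections(v, g)
  for (i in 1:12) expect_identical(back[[i]], mats[[i]])
  # 0-based (section 2, row 0, col 0) -> 0-based index 2592
  expect_identical(v[2592 + 1], mats[[3]][1, 1])
  # missing section -> NA block
  mats[[4]] <- matrix(NA_real_, 36, 36)
  v2 <- section_to_grid_vector(mats, g)
  expect_true(all(is.na(v2[(3 * 1296 + 1):(4 * 1296)])))
  expect_error(section_to_grid_vector(mats[1:3], g), "expected 12")
  expect_error(section_to_grid_vector(c(mats[1:11], list(matrix(0, 2, 2))), g),
               "shape")
})
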