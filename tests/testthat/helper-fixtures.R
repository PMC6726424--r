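# small fast geometry shared across tests: 12 x 12 bins x 3 sections
small_grid <- function() grid_spec(n_ml = 12, n_dv = 12, n_sections = 3)

small_truth <- function(n_subtypes = 2, n_genes = 8, seed = 5) {
  generate_ground_truth(n_subtypes, n_genes, small_grid(), seed = seed,
                        domain_sigma_um = 80, ap_sigma_sections = 1)
}

# spatial_matrix built directly from a values matrix (bypasses imaging)
matrix_from_values <- function(values, grid) {
  rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  build_matrix(stats::setNames(
    lapply(seq_len(nrow(values)), function(i) values[i, ]),
    rownames(values)), grid)
}

# FISH fixture with exact planted counts: `n_total` cells pass both gates,
# `n_positive` of them are target-positive, plus `n_ungated` cells that
# fail the gates
make_fish_fixture <- function(n_total, n_positive, target,
                              gates = c("Slc6a4", "B19N"), n_ungated = 10) {
  n <- n_total + n_ungated
  tab <- data.frame(cell_id = sprintf("c%04d", seq_len(n)),
                    x_um = 0, y_um = 0, ap_section = 1L)
  for (g in gates) tab[[g]] <- c(rep(5L, n_total), rep(1L, n_ungated))
  tab[[target]] <- c(rep(6L, n_positive), rep(0L, n - n_positive))
  tab
}

# planted spot fields with guaranteed minimum separation (poisson-disk by
# rejection), in um over a w x h field
planted_positions <- function(n, w_um, h_um, min_sep_um, margin_um = 30) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    x <- stats::runif(1, margin_um, w_um - margin_um)
    y <- stats::runif(1, margin_um, h_um - margin_um)
    if (length(xs) == 0 ||
        min((xs - x)^2 + (ys - y)^2) >= min_sep_um^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x_um = xs, y_um = ys)
}

# greedy one-to-one matching of detections to planted positions within a
# radius; returns c(tp, fp, fn)
match_spots <- function(detected, planted, radius_um) {
  used <- rep(FALSE, nrow(planted))
  tp <- 0L
  for (k in seq_len(nrow(detected))) {
    if (nrow(planted) == 0) break
    d2 <- (planted$x_um - detected$x_um[k])^2 +
      (planted$y_um - detected$y_um[k])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) == 1 && d2[j] <= radius_um^2) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(detected) - tp, fn = nrow(planted) - tp)
}
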