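#' Call probe positivity from a puncta count
#'
#' A cell is positive for a probe when it carries at least `min_puncta`
#' puncta (the "minimum of 3 puncta" rule by default, read inclusively).
#'
#' @param count Nonnegative integer puncta count(s); vectorized.
#' @param min_puncta Positivity threshold (default 3).
#' @return Logical vector.
#' @export
call_positive <- function(count, min_puncta = 3) {
  if (any(count < 0)) stop("puncta counts must be >= 0", call. = FALSE)
  count >= min_puncta
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Co-expression proportion in a gated cell population
#'
#' Gates the table to cells positive for every gate probe (e.g. the
#' serotonergic marker and the rabies transcript), then reports how many
#' of those also express the target probe. The percentage is rounded
#' half-away-from-zero to `rounding` decimals, matching whole-number
#' reporting conventions.
#'
#' @param table A FISH cell table (one puncta-count column per probe; see
#'   [simulate_fish_table()]).
#' @param gate_probes Character vector of gate probe columns (conjunctive,
#'   order-independent).
#' @param target_probe Target probe column.
#' @param min_puncta Positivity threshold applied to every probe; a named
#'   numeric vector overrides it per probe.
#' @param rounding Decimals for the percentage.
#' @return List with `n_positive`, `n_total`, `percent`.
#' @export
coexpression_proportion <- function(table, gate_probes, target_probe,
                                    min_puncta = 3, rounding = 0) {
  probes <- c(gate_probes, target_probe)
  missing_p <- setdiff(probes, names(table))
  if (length(missing_p) > 0)
    stop(sprintf("probe column(s) absent: %s",
                 paste(missing_p, collapse = ", ")), call. = FALSE)
  thr <- function(p) {
    if (!is.null(names(min_puncta)) && p %in% names(min_puncta))
      min_puncta[[p]] else unname(min_puncta[1])
  }
  gated <- rep(TRUE, nrow(table))
  for (p in gate_probes)
    gated <- gated & call_positive(table[[p]], thr(p))
  n_total <- sum(gated)
  if (n_total == 0)
    stop("degenerate input: no cell passes every gate (not a 0% result)",
         call. = FALSE)
  n_pos <- sum(gated & call_positive(table[[target_probe]], thr(target_probe)))
  list(n_positive = n_pos, n_total = n_total,
       percent = round_half_away(100 * n_pos / n_total, rounding))
}

#' Summarize a panel of FISH experiments
#'
#' One row per target probe, each computed from its own experiment table
#' and gating plan (separate probe sets are run on separate cell sets).
#'
#' @param tables Named list of FISH cell tables, keyed by experiment.
#' @param plan data.frame with columns `table` (experiment key), `target`
#'   (target probe) and `gates` (comma-separated gate probes).
#' @param min_puncta,rounding Passed to [coexpression_proportion()].
#' @return data.frame with columns `target`, `n_positive`, `n_total`,
#'   `percent`.
#' @export
summarize_panel <- function(tables, plan, min_puncta = 3, rounding = 0) {
  stopifnot(all(c("table", "target", "gates") %in% names(plan)))
  if (anyDuplicated(plan$target))
    stop("duplicate target row(s) in panel plan", call. = FALSE)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    tab <- tables[[plan$table[i]]]
    if (is.null(tab))
      stop(sprintf("experiment table '%s' not supplied", plan$table[i]),
           call. = FALSE)
    gates <- trimws(strsplit(plan$gates[i], ",")[[1]])
    res <- coexpression_proportion(tab, gates, plan$target[i],
                                   min_puncta = min_puncta,
                                   rounding = rounding)
    data.frame(target = plan$target[i], n_positive = res$n_positive,
               n_total = res$n_total, percent = res$percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
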