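# Within-stratum label permutation test for a global excess of enriched sets.
#
# Case-control status is shuffled between CNVs from the same study and chip,
# preserving each stratum's case/control CNV totals, and the whole battery of
# set tests is re-run on every permuted dataset. The permutation unit is the
# CNV, not the individual, matching the per-CNV regression.

#' Permute case-control labels within strata
#'
#' Reassigns the phenotype labels uniformly at random within each
#' study-by-chip stratum; each stratum's multiset of labels (and hence its
#' case/control CNV counts) is preserved exactly.
#'
#' @param cnvs CNV tibble.
#' @return The same tibble with `phenotype` permuted within strata.
#' @export
permute_labels <- function(cnvs) {
  validate_cnvs(cnvs)
  strat <- stratum_of(cnvs)
  y <- cnvs$phenotype
  for (s in levels(strat)) {
    idx <- which(strat == s)
    y[idx] <- y[idx][sample.int(length(idx))]
  }
  cnvs$phenotype <- y
  cnvs
}

# all distinct within-stratum label assignments for tiny inputs (used by the
# exhaustive mode); returns a matrix, one column per assignment
enumerate_label_assignments <- function(cnvs) {
  strat <- stratum_of(cnvs)
  per_stratum <- map(levels(strat), function(s) {
    idx <- which(strat == s)
    k <- sum(cnvs$phenotype[idx])
    case_sets <- utils::combn(length(idx), k, simplify = FALSE)
    map(case_sets, function(cs) {
      y <- integer(length(idx))
      y[cs] <- 1L
      y
    })
  })
  grids <- expand.grid(map(per_stratum, seq_along))
  idx_by_stratum <- map(levels(strat), function(s) which(strat == s))
  out <- matrix(0L, nrow(cnvs), nrow(grids))
  for (j in seq_len(nrow(grids))) {
    for (s in seq_along(per_stratum)) {
      out[idx_by_stratum[[s]], j] <- per_stratum[[s]][[grids[j, s]]]
    }
  }
  out
}

#' Permutation test for an excess of enriched gene sets
#'
#' Counts how many sets reach one-sided enrichment p below each threshold in
#' the observed labels (`n_obs`), re-runs the full battery on label-permuted
#' data to obtain the expected count (`n_exp`, the mean permuted count), and
#' reports the empirical probability of a permuted count reaching `n_obs`.
#' A zero count is reported as the bound `< 1/n_perm` in `p_report`.
#'
#' @param cnvs Annotated CNV tibble (one analysis).
#' @param sets Named list of gene sets.
#' @param thresholds P-value thresholds to count against (default
#'   `c(0.01, 0.001)`).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed; permutation j uses a substream seed derived
#'   deterministically from it, so results do not depend on execution order.
#' @param exhaustive Enumerate every distinct within-stratum assignment
#'   instead of sampling (tiny inputs only); `n_exp` and the empirical p are
#'   then exact.
#' @param n_comparisons Bonferroni factor for `p_adj` over the reported
#'   threshold-by-analysis combinations (default: number of thresholds).
#' @return A tibble of class `cnv_excess`, one row per threshold: `p_thr`,
#'   `n_sets`, `n_obs`, `n_exp`, `p_empirical`, `p_report`, `p_adj`,
#'   `n_perm`.
#' @export
excess_enrichment_test <- function(cnvs, sets, thresholds = c(0.01, 0.001),
                                   n_perm = 1000, seed = 1,
                                   exhaustive = FALSE,
                                   n_comparisons = length(thresholds)) {
  if (!exhaustive && n_perm < 1) abort("n_perm must be >= 1")
  validate_sets(sets)
  d <- build_design(cnvs, list())
  H <- hit_count_matrix(d$rows, sets)
  qa <- qr(d$X)
  strat <- stratum_of(d$rows)
  p_real <- enrichment_pvec(d$X, d$y, H, qa)
  n_obs <- vapply(thresholds, function(t) sum(p_real < t), integer(1))

  if (exhaustive) {
    Y <- enumerate_label_assignments(d$rows)
    counts <- matrix(NA_real_, ncol(Y), length(thresholds))
    for (j in seq_len(ncol(Y))) {
      pj <- enrichment_pvec(d$X, Y[, j], H, qa)
      counts[j, ] <- vapply(thresholds, function(t) sum(pj < t), integer(1))
    }
    n_used <- ncol(Y)
  } else {
    seeds <- derive_seeds(seed, n_perm)
    idx_by_stratum <- map(levels(strat), function(s) which(strat == s))
    counts <- matrix(NA_real_, n_perm, length(thresholds))
    for (j in seq_len(n_perm)) {
      set.seed(seeds[j])
      yj <- d$y
      for (idx in idx_by_stratum) {
        yj[idx] <- yj[idx][sample.int(length(idx))]
      }
      pj <- enrichment_pvec(d$X, yj, H, qa)
      counts[j, ] <- vapply(thresholds, function(t) sum(pj < t), integer(1))
    }
    n_used <- n_perm
  }

  n_exp <- colMeans(counts)
  p_emp <- vapply(seq_along(thresholds), function(k) {
    mean(counts[, k] >= n_obs[k])
  }, numeric(1))
  out <- tibble(
    p_thr = thresholds,
    n_sets = length(sets),
    n_obs = n_obs,
    n_exp = n_exp,
    p_empirical = p_emp,
    p_report = ifelse(p_emp == 0, paste0("< ", format(1 / n_used)),
      format(p_emp)),
    p_adj = pmin(1, pmax(p_emp, 1 / n_used) * n_comparisons),
    n_perm = n_used
  )
  class(out) <- c("cnv_excess", class(out))
  out
}
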