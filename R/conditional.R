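# Stepwise minimal-set selection, conditional enrichment scans, and CNV
# burden analyses (size versus genes hit, total or within the associated
# union set).

#' Stepwise selection of a minimal explanatory set of terms
#'
#' Greedy forward selection over candidate gene sets: at each step every
#' remaining candidate is tested for residual enrichment conditional on the
#' sets already selected; the candidate with the smallest residual p is added
#' while that p is below `alpha`. Ties are broken by smaller p, then by set
#' name. Selection stops when no remaining candidate shows residual
#' association.
#'
#' @param cnvs Annotated CNV tibble (one analysis).
#' @param candidate_sets Named list of candidate gene sets (typically the
#'   sets surviving multiple-testing correction).
#' @param alpha Stepwise residual-p threshold (default 0.05, uncorrected).
#' @param analysis Which CNVs to analyze (`"combined"`, `"del"`, `"dup"`).
#' @return A list of class `cnv_minimal_set`: `selected` (ordered set
#'   names), `steps` (tibble of all per-step residual p values, for audit),
#'   `stopping_reason`, `analysis`.
#' @export
minimal_set_selection <- function(cnvs, candidate_sets, alpha = 0.05,
                                  analysis = c("combined", "del", "dup")) {
  analysis <- match.arg(analysis)
  validate_sets(candidate_sets)
  selected <- character(0)
  steps <- list()
  remaining <- candidate_sets
  reason <- if (length(remaining) == 0) "no candidates" else NULL
  step <- 0L
  while (length(remaining) > 0) {
    step <- step + 1L
    res <- set_enrichment_test(cnvs, remaining, analysis = analysis,
      conditioning = candidate_sets[selected], n_tests = 1)
    res <- arrange(res, .data$p_one_sided, .data$set_name)
    steps[[step]] <- mutate(select(res, "set_name", "p_one_sided"),
      step = step, .before = 1)
    if (res$p_one_sided[1] >= alpha) {
      reason <- "no residual association"
      break
    }
    pick <- res$set_name[1]
    selected <- c(selected, pick)
    remaining <- remaining[setdiff(names(remaining), pick)]
    if (length(remaining) == 0) reason <- "all candidates selected"
  }
  structure(
    list(selected = selected, steps = bind_rows(steps),
      stopping_reason = reason, analysis = analysis, alpha = alpha),
    class = "cnv_minimal_set"
  )
}

#' @export
print.cnv_minimal_set <- function(x, ...) {
  cat("Minimal explanatory set (", x$analysis, " analysis)\n", sep = "")
  if (length(x$selected) == 0) cat("  no sets selected\n")
  else cat(paste0("  ", seq_along(x$selected), ". ", x$selected, "\n"), sep = "")
  cat("  stopping reason:", x$stopping_reason, "\n")
  invisible(x)
}

#' Enrichment scan conditional on a fixed set of terms
#'
#' Re-tests a battery of gene sets with the hit counts of the conditioning
#' sets (typically a minimal explanatory set) added to the baseline model, to
#' ask whether any residual enrichment remains beyond them.
#'
#' @param cnvs Annotated CNV tibble.
#' @param scan_sets Named list of sets to scan.
#' @param conditioning Named list of conditioning sets (fixed across the
#'   scan).
#' @param n_tests Bonferroni factor (default: number of scan sets).
#' @inheritParams set_enrichment_test
#' @return A `cnv_enrichment` tibble over `scan_sets`.
#' @export
conditional_scan <- function(cnvs, scan_sets, conditioning = list(),
                             n_tests = NULL,
                             analysis = c("combined", "del", "dup")) {
  set_enrichment_test(cnvs, scan_sets, analysis = match.arg(analysis),
    conditioning = conditioning, n_tests = n_tests)
}

#' CNV burden analysis: size and genes hit as predictors of case status
#'
#' For each requested predictor, tests whether adding it to a logistic model
#' of case-control status already containing the stratum covariates (and any
#' conditioning predictors) reduces the deviance, with a one-sided
#' signed-root p toward case excess. Predictors: `"size"` (CNV length in
#' kb), `"n_genes_total"` (genes hit), and `"n_genes_set"` (genes hit within
#' `burden_set`, e.g. the CNS_SZ union set).
#'
#' @param cnvs Annotated CNV tibble.
#' @param predictors Character vector from
#'   `c("size", "n_genes_total", "n_genes_set")`.
#' @param conditioning Character vector of predictors (same vocabulary) to
#'   include in the baseline model.
#' @param burden_set Character vector of gene ids defining `"n_genes_set"`.
#' @param analysis Which CNVs to analyze.
#' @return A tibble of class `cnv_burden`, one row per predictor: `analysis`,
#'   `predictor`, `conditioning`, `beta`, `delta_deviance`, `p_one_sided`,
#'   `degenerate`.
#' @export
burden_analysis <- function(cnvs, predictors = c("size", "n_genes_total"),
                            conditioning = character(0), burden_set = NULL,
                            analysis = c("combined", "del", "dup")) {
  analysis <- match.arg(analysis)
  rows <- filter_analysis(cnvs, analysis)
  allowed <- c("size", "n_genes_total", "n_genes_set")
  if (!all(c(predictors, conditioning) %in% allowed)) {
    abort(paste0("predictors must be among: ", paste(allowed, collapse = ", ")))
  }
  if (("n_genes_set" %in% c(predictors, conditioning)) && is.null(burden_set)) {
    abort("burden_set must be supplied to use the 'n_genes_set' predictor")
  }
  pred_col <- function(rows, p) {
    switch(p,
      size = rows$size_kb,
      n_genes_total = as.numeric(rows$n_genes_total),
      n_genes_set = as.numeric(set_hit_count(rows, burden_set))
    )
  }
  # baseline: intercept + strata + conditioning predictors
  d <- build_design(rows, list(), size = FALSE, total_genes = FALSE)
  Xa <- d$X
  for (p in conditioning) {
    Xa <- cbind(Xa, pred_col(d$rows, p))
    colnames(Xa)[ncol(Xa)] <- p
  }
  fit_a <- fit_logit_mat(Xa, d$y)
  res <- map(predictors, function(p) {
    r <- deviance_test_one(Xa, d$y, pred_col(d$rows, p), fit_a)
    tibble(analysis = analysis, predictor = p,
      conditioning = paste(conditioning, collapse = "+"),
      beta = r$beta, delta_deviance = r$delta, p_one_sided = r$p,
      degenerate = r$degenerate)
  })
  out <- bind_rows(res)
  class(out) <- c("cnv_burden", class(out))
  out
}
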