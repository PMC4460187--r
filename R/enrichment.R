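# Nested logistic deviance test for gene-set enrichment in case CNVs.
#
# Baseline model (a):  logit(pr(case)) = stratum + size + total genes hit
# Alternative (b):     model (a) + number of genes hit in the gene set
# The test statistic is the signed root of the deviance drop,
# z = sign(beta_set) * sqrt(dev_a - dev_b), and the one-sided p value
# 1 - pnorm(z) is small only for enrichment in case CNVs.

filter_analysis <- function(cnvs, analysis) {
  switch(analysis,
    combined = cnvs,
    del = filter(cnvs, .data$copy_state == "del"),
    dup = filter(cnvs, .data$copy_state == "dup"),
    abort("analysis must be one of 'combined', 'del', 'dup'")
  )
}

# one nested deviance comparison given the baseline fit; h is the added
# hit-count column. Returns the degenerate result (p = 0.5) when h is
# constant or (numerically) collinear with the baseline design; `qa` is the
# prefactored qr(Xa), reused across sets.
deviance_test_one <- function(Xa, y, h, fit_a, qa = qr(Xa)) {
  degenerate <- list(delta = 0, beta = 0, se = NA_real_, p = 0.5,
    degenerate = TRUE)
  if (sd(h) == 0) return(degenerate)
  resid_h <- qr.resid(qa, h)
  if (sum(resid_h^2) <= 1e-10 * sum((h - mean(h))^2)) return(degenerate)
  Xb <- cbind(Xa, set_hit = h)
  start <- c(ifelse(is.na(fit_a$coefficients), 0, fit_a$coefficients), 0)
  fit_b <- fit_logit_mat(Xb, y, start = start)
  beta <- fit_b$coefficients[["set_hit"]]
  if (is.na(beta)) return(degenerate)
  delta <- max(fit_a$deviance - fit_b$deviance, 0)
  z <- sign(beta) * sqrt(delta)
  list(delta = delta, beta = beta, se = fit_b$se[["set_hit"]],
    p = pnorm(z, lower.tail = FALSE), degenerate = FALSE)
}

# p values for every column of hit-count matrix H under phenotype y;
# the permutation engine's fast path (design matrices prebuilt).
enrichment_pvec <- function(Xa, y, H, qa = qr(Xa)) {
  fit_a <- fit_logit_mat(Xa, y)
  vapply(seq_len(ncol(H)), function(j) {
    deviance_test_one(Xa, y, H[, j], fit_a, qa)$p
  }, numeric(1))
}

#' Gene-set enrichment test for case CNVs
#'
#' For each gene set, compares nested logistic regressions of per-CNV
#' case-control status with and without the per-CNV count of hit set members,
#' adjusting for study-by-chip stratum, CNV size and total genes hit. The
#' one-sided signed-root-deviance p value is small only when the set is
#' enriched in case CNVs; Bonferroni adjustment uses the caller-supplied test
#' count so a battery can be corrected across several analyses at once.
#'
#' @param cnvs Annotated CNV tibble (see [annotate_cnvs()]).
#' @param sets Named list of gene sets (character vectors of gene ids), or a
#'   single character vector treated as one set.
#' @param analysis `"combined"` (all CNVs), `"del"` (deletions only) or
#'   `"dup"` (duplications only).
#' @param conditioning Named list of gene sets whose hit counts enter the
#'   baseline model as covariates (used by conditional scans).
#' @param n_tests Number of tests for Bonferroni correction (default: number
#'   of sets tested here).
#' @param firth When `TRUE`, report odds ratios and confidence intervals from
#'   a Jeffreys-penalized fit, which stays finite under separation; the
#'   p value is always the maximum-likelihood deviance test.
#' @return A tibble of class `cnv_enrichment`, one row per set: `set_name`,
#'   `analysis`, `n_gene`, `delta_deviance`, `beta_set`, `p_one_sided`,
#'   `p_adj`, `odds_ratio`, `ci_lo`, `ci_hi`, `n_case_cnv`, `n_ctrl_cnv`,
#'   `degenerate`.
#' @export
set_enrichment_test <- function(cnvs, sets,
                                analysis = c("combined", "del", "dup"),
                                conditioning = list(),
                                n_tests = NULL, firth = FALSE) {
  analysis <- match.arg(analysis)
  if (is.character(sets)) sets <- list(set = sets)
  validate_sets(sets)
  if (is.null(n_tests)) n_tests <- length(sets)
  rows <- filter_analysis(cnvs, analysis)
  d <- build_design(rows, conditioning)
  H <- hit_count_matrix(d$rows, sets)
  fit_a <- fit_logit_mat(d$X, d$y)
  qa <- qr(d$X)
  res <- map(seq_along(sets), function(j) {
    r <- deviance_test_one(d$X, d$y, H[, j], fit_a, qa)
    if (firth && !r$degenerate) {
      fb <- fit_logit_firth(cbind(d$X, set_hit = H[, j]), d$y)
      r$beta_or <- fb$coefficients[["set_hit"]]
      r$se_or <- fb$se[["set_hit"]]
    } else {
      r$beta_or <- r$beta
      r$se_or <- r$se
    }
    r
  })
  out <- tibble(
    set_name = names(sets),
    analysis = analysis,
    n_gene = lengths(sets),
    delta_deviance = map_dbl(res, "delta"),
    beta_set = map_dbl(res, "beta"),
    p_one_sided = map_dbl(res, "p"),
    p_adj = bonferroni(map_dbl(res, "p"), n_tests),
    odds_ratio = ifelse(map_lgl(res, "degenerate"), 1,
      exp(map_dbl(res, "beta_or"))),
    ci_lo = ifelse(map_lgl(res, "degenerate"), 1,
      exp(map_dbl(res, "beta_or") - qnorm(0.975) * map_dbl(res, "se_or"))),
    ci_hi = ifelse(map_lgl(res, "degenerate"), 1,
      exp(map_dbl(res, "beta_or") + qnorm(0.975) * map_dbl(res, "se_or"))),
    n_case_cnv = sum(d$y),
    n_ctrl_cnv = sum(1 - d$y),
    degenerate = map_lgl(res, "degenerate")
  )
  class(out) <- c("cnv_enrichment", class(out))
  out
}

#' Single-gene enrichment test
#'
#' The set test with each "set" restricted to a single gene, so the added
#' covariate is the 0/1 indicator of the CNV hitting that gene.
#'
#' @param cnvs Annotated CNV tibble.
#' @param genes Character vector of gene ids to test.
#' @inheritParams set_enrichment_test
#' @return A `cnv_enrichment` tibble, one row per gene (`set_name` holds the
#'   gene id).
#' @export
single_gene_test <- function(cnvs, genes,
                             analysis = c("combined", "del", "dup"),
                             conditioning = list(), n_tests = NULL,
                             firth = FALSE) {
  sets <- setNames(map(genes, identity), genes)
  set_enrichment_test(cnvs, sets, analysis = match.arg(analysis),
    conditioning = conditioning, n_tests = n_tests, firth = firth)
}

#' Bonferroni correction
#'
#' Multiplies p values by the number of tests performed, capping at 1. The
#' test count is caller-supplied so that a battery tested under several
#' analyses can be corrected for all of them (e.g. 134 sets x 3 analyses =
#' 402 tests).
#'
#' @param p Numeric vector of p values in (0, 1].
#' @param n_tests Number of tests (>= 1).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1, all(p > 0 & p <= 1))
  pmin(1, p * n_tests)
}

#' Genes driving associated gene sets
#'
#' For each set passing the adjusted-p threshold, runs single-gene tests on
#' its member genes and reports those with uncorrected single-gene p below
#' `alpha_gene`, sorted by set then p.
#'
#' @param results `cnv_enrichment` tibble for one analysis.
#' @param cnvs Annotated CNV tibble for the same analysis.
#' @param sets Named list of gene sets the results refer to.
#' @param alpha_adj Adjusted-p threshold for a set to be reported (default
#'   0.05).
#' @param alpha_gene Uncorrected single-gene p threshold (default 0.05).
#' @return A tibble with columns `set_name`, `gene_id`, `p`.
#' @export
extract_top_genes <- function(results, cnvs, sets, alpha_adj = 0.05,
                              alpha_gene = 0.05) {
  validate_sets(sets)
  pass <- results$set_name[results$p_adj < alpha_adj]
  out <- map(pass, function(s) {
    analysis <- results$analysis[results$set_name == s][1]
    g <- single_gene_test(cnvs, sets[[s]], analysis = analysis)
    g <- filter(g, .data$p_one_sided < alpha_gene)
    tibble(set_name = s, gene_id = g$set_name, p = g$p_one_sided)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(set_name = character(0), gene_id = character(0),
      p = numeric(0)))
  }
  arrange(out, .data$set_name, .data$p)
}
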