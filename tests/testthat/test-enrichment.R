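# Nested logistic deviance test: oracle equivalence, symmetry, degeneracy,
# Bonferroni arithmetic, single-gene variant, top-gene extraction.

rand_ann <- function(n, n_strata = 2, pool = sprintf("g%02d", 1:30)) {
  gh <- lapply(seq_len(n), function(i) sample(pool, sample(0:8, 1)))
  st <- sample(LETTERS[seq_len(n_strata)], n, replace = TRUE)
  out <- ann_tbl(gh, phenotype = sample(0:1, n, replace = TRUE), study = st)
  out$size_kb <- runif(n, 100, 500)
  out$end <- out$start + out$size_kb * 1000
  out
}

test_that("intercept-only fit recovers the closed-form case-fraction logit", {
  rows <- ann_tbl(rep(list("g1"), 100), phenotype = rep(c(1L, 0L), c(30, 70)))
  # every covariate is constant here and is dropped
  fit <- suppressWarnings(fit_cnv_logistic(rows))
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(30 / 70),
    tolerance = 1e-7)
  expect_true(fit$converged)
  g <- glance(fit)
  expect_equal(g$n_case, 30)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
})

test_that("the enrichment test matches the independent grid-search ML oracle", {
  # 20 case CNVs (10 hitting the set) vs 20 controls (2 hitting), one
  # stratum, equal sizes and totals: 2 free parameters
  rows <- balanced_ann(
    h_case = rep(c(1, 0), c(10, 10)),
    h_ctrl = rep(c(1, 0), c(2, 18)),
    set_genes = "m1"
  )
  res <- suppressWarnings(set_enrichment_test(rows, list(S = "m1")))

  h <- c(rep(c(1, 0), c(10, 10)), rep(c(1, 0), c(2, 18)))
  y <- rep(c(1, 0), c(20, 20))
  or_b <- grid_ml_oracle(cbind(1, h), y)
  dev_a <- -2 * 40 * log(0.5) # intercept-only ML at case fraction 1/2
  z <- sign(or_b$beta[2]) * sqrt(dev_a - or_b$deviance)
  expect_equal(res$delta_deviance, dev_a - or_b$deviance, tolerance = 1e-6)
  expect_equal(res$p_one_sided, unname(1 - pnorm(z)), tolerance = 1e-6)
  expect_equal(res$odds_ratio, unname(exp(or_b$beta[2])), tolerance = 1e-4)
  expect_gt(res$odds_ratio, 1) # cases enriched by construction

  # 3 free parameters: intercept + size + set hit
  set.seed(43)
  rows3 <- rows
  rows3$size_kb <- round(runif(40, 100, 400))
  res3 <- suppressWarnings(set_enrichment_test(rows3, list(S = "m1")))
  Xa <- cbind(1, rows3$size_kb)
  Xb <- cbind(Xa, h)
  oa <- grid_ml_oracle(Xa, y)
  ob <- grid_ml_oracle(Xb, y)
  expect_equal(res3$delta_deviance, oa$deviance - ob$deviance,
    tolerance = 1e-6)
  zb <- sign(ob$beta[3]) * sqrt(oa$deviance - ob$deviance)
  expect_equal(res3$p_one_sided, unname(1 - pnorm(zb)), tolerance = 1e-6)
})

test_that("adding a covariate never increases deviance and delta_deviance is nonnegative", {
  set.seed(47)
  for (rep in 1:10) {
    rows <- rand_ann(80)
    s <- sample(sprintf("g%02d", 1:30), 10)
    res <- suppressWarnings(set_enrichment_test(rows, list(S = s)))
    expect_gte(res$delta_deviance, 0)
    f_a <- suppressWarnings(fit_cnv_logistic(rows))
    f_b <- suppressWarnings(fit_cnv_logistic(rows, set = s))
    expect_lte(f_b$deviance, f_a$deviance + 1e-8)
  }
})

test_that("swapping every phenotype label maps p to 1-p and OR to 1/OR", {
  set.seed(53)
  for (rep in 1:5) {
    rows <- rand_ann(60)
    s <- sample(sprintf("g%02d", 1:30), 8)
    res <- suppressWarnings(set_enrichment_test(rows, list(S = s)))
    swapped <- rows
    swapped$phenotype <- 1L - rows$phenotype
    res2 <- suppressWarnings(set_enrichment_test(swapped, list(S = s)))
    expect_equal(res2$p_one_sided, 1 - res$p_one_sided, tolerance = 1e-6)
    expect_equal(res2$odds_ratio, 1 / res$odds_ratio, tolerance = 1e-6)
    expect_equal(res2$delta_deviance, res$delta_deviance, tolerance = 1e-6)
  }
})

test_that("a constant or collinear set covariate yields the flagged degenerate result", {
  rows <- balanced_ann(h_case = rep(1, 10), h_ctrl = rep(1, 10),
    set_genes = "m1")
  res <- suppressWarnings(set_enrichment_test(rows, list(S = "m1")))
  expect_true(res$degenerate)
  expect_equal(res$p_one_sided, 0.5)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$delta_deviance, 0)

  # conditioning on the set itself makes its covariate collinear
  set.seed(59)
  rows <- rand_ann(60)
  s <- sample(sprintf("g%02d", 1:30), 8)
  res <- suppressWarnings(set_enrichment_test(rows, list(S = s),
    conditioning = list(S0 = s)))
  expect_true(res$degenerate)
  expect_equal(res$p_one_sided, 0.5)
})

test_that("single-gene testing is the set test on a singleton set", {
  set.seed(61)
  rows <- rand_ann(70)
  genes <- sprintf("g%02d", 1:6)
  res_g <- suppressWarnings(single_gene_test(rows, genes))
  for (g in genes) {
    res_s <- suppressWarnings(set_enrichment_test(rows, setNames(list(g), g),
      n_tests = length(genes)))
    expect_equal(res_g[res_g$set_name == g, ], res_s, ignore_attr = TRUE)
  }
  # a gene hit by no CNV is degenerate
  res0 <- suppressWarnings(single_gene_test(rows, "absent_gene"))
  expect_true(res0$degenerate)
  expect_equal(res0$p_one_sided, 0.5)
})

test_that("a set hit only in cases keeps a finite deviance test and Firth gives finite intervals", {
  rows <- balanced_ann(h_case = rep(c(1, 0), c(6, 6)), h_ctrl = rep(0, 12),
    set_genes = "m1")
  res <- suppressWarnings(set_enrichment_test(rows, list(S = "m1")))
  expect_false(res$degenerate)
  expect_true(is.finite(res$delta_deviance) && res$delta_deviance > 0)
  expect_lt(res$p_one_sided, 0.5)
  resf <- suppressWarnings(set_enrichment_test(rows, list(S = "m1"),
    firth = TRUE))
  expect_true(is.finite(resf$odds_ratio))
  expect_true(is.finite(resf$ci_hi))
  expect_equal(resf$p_one_sided, res$p_one_sided) # p always from the ML test
})

test_that("Bonferroni correction reproduces the worked battery arithmetic", {
  expect_equal(signif(bonferroni(4.3e-9, 402), 2), 1.7e-6)
  expect_equal(signif(bonferroni(3.0e-6, 402), 2), 0.0012)
  expect_equal(bonferroni(0.01, 402), 1)
  expect_error(bonferroni(0, 402))
})

test_that("one-sided null p values are roughly uniform on null data", {
  set.seed(67)
  p <- replicate(400, {
    rows <- rand_ann(50, n_strata = 1)
    s <- sample(sprintf("g%02d", 1:30), 8)
    suppressWarnings(set_enrichment_test(rows, list(S = s)))$p_one_sided
  })
  expect_gt(mean(p < 0.05), 0.01)
  expect_lt(mean(p < 0.05), 0.10)
  expect_gt(mean(p), 0.40)
  expect_lt(mean(p), 0.60)
})

test_that("result invariants hold: p_adj >= p, CI brackets the OR", {
  set.seed(71)
  rows <- rand_ann(120)
  sets <- setNames(lapply(1:6, function(i) sample(sprintf("g%02d", 1:30), 7)),
    sprintf("S%d", 1:6))
  res <- suppressWarnings(set_enrichment_test(rows, sets, n_tests = 18))
  expect_true(all(res$p_adj >= res$p_one_sided))
  expect_true(all(res$odds_ratio > 0))
  ok <- !res$degenerate & is.finite(res$ci_lo)
  expect_true(all(res$ci_lo[ok] <= res$odds_ratio[ok]))
  expect_true(all(res$ci_hi[ok] >= res$odds_ratio[ok]))
})

test_that("top-gene extraction equals the brute-force double loop", {
  set.seed(73)
  pool <- sprintf("g%02d", 1:20)
  rows <- rand_ann(150, n_strata = 1, pool = pool)
  sets <- list(A = pool[1:6], B = pool[7:12], C = pool[13:20])
  res <- suppressWarnings(set_enrichment_test(rows, sets, n_tests = 3))
  res$p_adj <- c(0.01, 0.2, 0.04) # fix which sets pass for the audit
  got <- suppressWarnings(extract_top_genes(res, rows, sets))
  want <- list()
  for (s in c("A", "C")) {
    for (g in sets[[s]]) {
      p <- suppressWarnings(single_gene_test(rows, g))$p_one_sided
      if (p < 0.05) want[[length(want) + 1]] <- tibble::tibble(
        set_name = s, gene_id = g, p = p)
    }
  }
  want <- if (length(want)) dplyr::arrange(dplyr::bind_rows(want),
    set_name, p) else tibble::tibble(set_name = character(0),
    gene_id = character(0), p = numeric(0))
  expect_equal(as.data.frame(got), as.data.frame(want))

  # no passing set, and passing set never hit -> empty tables
  res$p_adj <- rep(1, 3)
  expect_equal(nrow(suppressWarnings(extract_top_genes(res, rows, sets))), 0)
  sets2 <- c(sets, list(D = "never_hit"))
  res2 <- suppressWarnings(set_enrichment_test(rows, sets2, n_tests = 4))
  res2$p_adj <- c(1, 1, 1, 0.01)
  expect_equal(nrow(suppressWarnings(extract_top_genes(res2, rows, sets2))), 0)
})
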