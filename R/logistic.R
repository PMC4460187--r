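# Maximum-likelihood logistic fitting behind the enrichment tests.
#
# All tests in the package reduce to deviance comparisons between nested
# binomial GLMs fitted by IRLS (stats::glm.fit). The fast path works on
# prebuilt model matrices so a permutation run refits thousands of models
# without rebuilding design matrices.

MAXIT <- 50L
EPSILON <- 1e-10

# binomial deviance at fitted probabilities (labels are 0/1 here)
binom_deviance <- function(y, mu) {
  -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
}

# IRLS maximum-likelihood logistic fit on a model matrix. Newton steps with
# step-halving; aliased (rank-deficient) columns get NA coefficients, as in
# stats::glm. Capped at MAXIT iterations: under separation the deviance
# converges even though the coefficient diverges, and the deviance at the
# cap is used.
fit_logit_mat <- function(X, y, start = NULL, keep = NULL) {
  if (all(y == 1) || all(y == 0)) {
    abort("logistic fit needs at least one case and one control")
  }
  p <- ncol(X)
  if (is.null(keep)) keep <- seq_len(p)
  Xf <- if (length(keep) < p) X[, keep, drop = FALSE] else X
  beta <- if (!is.null(start)) {
    start[keep]
  } else {
    b <- numeric(length(keep))
    b[1] <- log(mean(y) / (1 - mean(y))) # designs carry an intercept first
    b
  }
  eta <- drop(Xf %*% beta)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  dev <- binom_deviance(y, mu)
  converged <- FALSE
  it <- 0L
  U_last <- NULL
  while (it < MAXIT) {
    it <- it + 1L
    w <- mu * (1 - mu)
    XtWX <- crossprod(Xf, Xf * w)
    U <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(U)) {
      if (it == 1L && length(keep) == p) {
        # exact collinearity: drop aliased columns (as stats::glm does)
        qrX <- qr(X)
        reduced <- sort(qrX$pivot[seq_len(qrX$rank)])
        if (length(reduced) < p) {
          return(fit_logit_mat(X, y, start = start, keep = reduced))
        }
      }
      break
    }
    U_last <- U
    score <- drop(crossprod(Xf, y - mu))
    step <- backsolve(U, backsolve(U, score, transpose = TRUE))
    dev_new <- Inf
    for (half in 0:20) {
      beta_try <- beta + step / 2^half
      eta <- drop(Xf %*% beta_try)
      mu_try <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
      dev_new <- binom_deviance(y, mu_try)
      if (is.finite(dev_new) && dev_new <= dev + 1e-8) break
    }
    beta <- beta_try
    mu <- mu_try
    if (abs(dev - dev_new) < EPSILON * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  cf <- setNames(rep(NA_real_, p), colnames(X))
  se <- cf
  cf[keep] <- beta
  if (!is.null(U_last)) {
    w <- mu * (1 - mu)
    cov <- tryCatch(chol2inv(chol(crossprod(Xf, Xf * w))),
      error = function(e) NULL)
    if (!is.null(cov)) se[keep] <- sqrt(diag(cov))
  }
  list(
    coefficients = cf, se = se, deviance = dev,
    converged = converged, n_iter = it, fitted = mu
  )
}

# Firth (Jeffreys-penalized) IRLS; finite estimates under separation
fit_logit_firth <- function(X, y, maxit = MAXIT, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- try(chol2inv(chol(XtWX)), silent = TRUE)
    if (inherits(inv, "try-error")) break
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  inv <- try(chol2inv(chol(XtWX)), silent = TRUE)
  se <- if (inherits(inv, "try-error")) rep(NA_real_, p) else sqrt(diag(inv))
  dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  list(coefficients = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
    deviance = dev, converged = it < maxit, n_iter = it)
}

# design matrix for the baseline model: intercept, stratum indicators,
# size, total genes, plus any conditioning hit-count columns.
# Strata that are all-case or all-control are dropped (rows removed) with a
# warning: their indicator perfectly predicts status.
build_design <- function(cnvs, conditioning = list(), size = TRUE,
                         total_genes = TRUE) {
  validate_cnvs(cnvs, annotated = TRUE)
  strat <- stratum_of(cnvs)
  tab <- table(strat, cnvs$phenotype)
  bad <- rownames(tab)[tab[, 1] == 0 | tab[, 2] == 0]
  keep <- !(as.character(strat) %in% bad)
  if (length(bad) > 0) {
    warn(paste0("dropping stratum/strata with no case-control contrast: ",
      paste(bad, collapse = ", ")))
  }
  rows <- cnvs[keep, , drop = FALSE]
  strat <- droplevels(strat[keep])
  X <- matrix(1, nrow(rows), 1, dimnames = list(NULL, "(Intercept)"))
  if (nlevels(strat) > 1) {
    S <- stats::model.matrix(~strat)[, -1, drop = FALSE]
    colnames(S) <- paste0("stratum", levels(strat)[-1])
    X <- cbind(X, S)
  }
  if (size) X <- cbind(X, size_kb = rows$size_kb)
  if (total_genes) X <- cbind(X, n_genes_total = rows$n_genes_total)
  for (nm in names(conditioning)) {
    X <- cbind(X, set_hit_count(rows, conditioning[[nm]]))
    colnames(X)[ncol(X)] <- paste0("cond_", nm)
  }
  drop_const <- if (ncol(X) > 1) {
    apply(X[, -1, drop = FALSE], 2, function(v) sd(v) == 0)
  } else logical(0)
  if (any(drop_const)) {
    warn(paste0("dropping constant covariate(s): ",
      paste(colnames(X)[-1][drop_const], collapse = ", ")))
    X <- X[, c(TRUE, !drop_const), drop = FALSE]
  }
  list(X = X, y = rows$phenotype, rows = rows, keep = which(keep))
}

#' Fit the covariate-adjusted CNV logistic model
#'
#' Fits `logit(pr(case)) = stratum + size_kb + n_genes_total [+ conditioning
#' hit counts] [+ set hit count]` by maximum likelihood, where stratum is the
#' study-by-chip combination. This is the baseline model of the enrichment
#' test; adding a gene-set hit-count column gives the alternative.
#'
#' @param cnvs Annotated CNV tibble.
#' @param set Optional character vector of gene ids; when supplied the model
#'   includes the per-CNV count of hit set members.
#' @param conditioning Named list of gene sets entering as extra hit-count
#'   covariates.
#' @param size,total_genes Include the CNV size (kb) / total-genes-hit
#'   covariates (default `TRUE`).
#' @param firth Use Jeffreys-penalized (Firth) estimation, which keeps
#'   estimates finite under separation (default `FALSE`).
#' @return An object of class `cnv_logit` with `tidy()` and `glance()`
#'   methods.
#' @export
fit_cnv_logistic <- function(cnvs, set = NULL, conditioning = list(),
                             size = TRUE, total_genes = TRUE, firth = FALSE) {
  d <- build_design(cnvs, conditioning, size, total_genes)
  X <- d$X
  if (!is.null(set)) {
    h <- set_hit_count(d$rows, set)
    if (sd(h) > 0) X <- cbind(X, set_hit = h)
    else warn("set hit count is constant; covariate dropped")
  }
  f <- if (firth) fit_logit_firth(X, d$y) else fit_logit_mat(X, d$y)
  structure(
    list(coefficients = f$coefficients, se = f$se, deviance = f$deviance,
      converged = f$converged, n_iter = f$n_iter, n = length(d$y),
      n_case = sum(d$y), n_ctrl = sum(1 - d$y), firth = firth,
      terms = colnames(X)),
    class = "cnv_logit"
  )
}

#' @export
print.cnv_logit <- function(x, ...) {
  cat("CNV logistic model (", if (x$firth) "Firth" else "ML", " fit)\n", sep = "")
  cat("  n =", x$n, "(", x$n_case, "cases /", x$n_ctrl, "controls )\n")
  cat("  deviance =", format(x$deviance), "; converged:", x$converged,
    "in", x$n_iter, "iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a fitted CNV logistic model
#'
#' @param x A `cnv_logit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: estimate, standard error,
#'   Wald statistic and two-sided p value.
#' @method tidy cnv_logit
#' @export
tidy.cnv_logit <- function(x, ...) {
  est <- x$coefficients
  tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(est / x$se),
    p.value = 2 * pnorm(-abs(unname(est / x$se)))
  )
}

#' Model-level summary of a fitted CNV logistic model
#'
#' @param x A `cnv_logit` object.
#' @param ... Unused.
#' @return A one-row tibble: deviance, convergence flag, iteration count and
#'   sample composition.
#' @method glance cnv_logit
#' @export
glance.cnv_logit <- function(x, ...) {
  tibble(deviance = x$deviance, converged = x$converged, n_iter = x$n_iter,
    nobs = x$n, n_case = x$n_case, n_ctrl = x$n_ctrl)
}
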