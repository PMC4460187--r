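# Independent oracles used to freeze expected values. These deliberately use
# naive algorithms (per-base scans, all-pairs closure, grid search) and never
# call the code paths they check.

# fixpoint merging by repeatedly joining an arbitrary mergeable pair; `order`
# seeds the pair choice so different merge orders can be exercised
merge_oracle_group <- function(df, order_seed = 1) {
  set.seed(order_seed)
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    n <- length(rows)
    if (n < 2) break
    pairs <- list()
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        a <- rows[[i]]; b <- rows[[j]]
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap < 0.5 * ((a$end - a$start) + (b$end - b$start))) {
          pairs[[length(pairs) + 1]] <- c(i, j)
        }
      }
    }
    if (length(pairs) == 0) break
    pick <- pairs[[sample.int(length(pairs), 1)]]
    a <- rows[[pick[1]]]; b <- rows[[pick[2]]]
    merged <- a
    merged$start <- min(a$start, b$start)
    merged$end <- max(a$end, b$end)
    merged$n_probes <- a$n_probes + b$n_probes
    rows[[pick[1]]] <- merged
    rows[[pick[2]]] <- NULL
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), c("start", "end", "n_probes")]
}

# bp of a call covered by the union of regions, counted base by base
coverage_oracle <- function(start, end, regions) {
  covered <- rep(FALSE, end - start)
  for (i in seq_len(nrow(regions))) {
    lo <- max(start, regions$start[i]); hi <- min(end, regions$end[i])
    if (hi > lo) covered[(lo - start + 1):(hi - start)] <- TRUE
  }
  sum(covered)
}

# all-pairs single-linkage clusters under >= recip reciprocal overlap
cluster_oracle <- function(cnvs, recip) {
  n <- nrow(cnvs)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (cnvs$chrom[i] != cnvs$chrom[j] ||
        cnvs$copy_state[i] != cnvs$copy_state[j]) next
      ov <- min(cnvs$end[i], cnvs$end[j]) - max(cnvs$start[i], cnvs$start[j])
      li <- cnvs$end[i] - cnvs$start[i]; lj <- cnvs$end[j] - cnvs$start[j]
      if (ov >= recip * li && ov >= recip * lj) adj[i, j] <- TRUE
    }
  }
  # transitive closure
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  match(apply(adj, 1, function(r) paste(which(r), collapse = ",")),
    unique(apply(adj, 1, function(r) paste(which(r), collapse = ","))))
}

# maximum-likelihood logistic fit by iterative grid refinement (no IRLS, no
# glm); works for up to 3 free parameters. Columns are rescaled to unit
# maximum absolute value so the search box is comparably conditioned on every
# axis; the window re-expands whenever the maximum lands on its edge.
grid_ml_oracle <- function(X, y, half_width = 10, rounds = 60, points = 15) {
  p <- ncol(X)
  scale <- apply(abs(X), 2, max)
  Xs <- sweep(X, 2, scale, "/")
  centre <- rep(0, p)
  width <- rep(half_width, p)
  loglik <- function(gamma) {
    eta <- drop(Xs %*% gamma)
    sum(y * eta - log1p(exp(eta)))
  }
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(k) {
      seq(centre[k] - width[k], centre[k] + width[k], length.out = points)
    })
    combos <- as.matrix(expand.grid(grids))
    ll <- apply(combos, 1, loglik)
    best <- combos[which.max(ll), ]
    on_edge <- vapply(seq_len(p), function(k) {
      best[k] <= centre[k] - width[k] + 1e-15 ||
        best[k] >= centre[k] + width[k] - 1e-15
    }, logical(1))
    centre <- best
    width <- ifelse(on_edge, width * 2, width * 2.5 / (points - 1))
  }
  list(beta = centre / scale, deviance = -2 * loglik(centre))
}

# every distinct within-stratum case-control assignment (columns), oracle for
# both the exhaustive and the sampled permutation machinery
all_label_assignments <- function(cnvs) {
  strat <- interaction(cnvs$study, cnvs$chip, drop = TRUE)
  per <- lapply(levels(strat), function(s) {
    idx <- which(strat == s)
    k <- sum(cnvs$phenotype[idx])
    lapply(utils::combn(length(idx), max(k, 0), simplify = FALSE), function(cs) {
      y <- integer(length(idx)); y[cs] <- 1L; y
    })
  })
  idx_by <- lapply(levels(strat), function(s) which(strat == s))
  grid <- expand.grid(lapply(per, seq_along))
  out <- matrix(0L, nrow(cnvs), nrow(grid))
  for (j in seq_len(nrow(grid))) {
    for (s in seq_along(per)) out[idx_by[[s]], j] <- per[[s]][[grid[j, s]]]
  }
  out
}
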