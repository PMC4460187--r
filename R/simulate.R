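# Synthetic case-control CNV study generator.
#
# Generates a toy genome (gene models, probe map, low-copy repeats), an
# overlapping gene-set battery, and per-stratum CNV datasets whose
# case-control labels are drawn from the same logistic model the enrichment
# test fits:
#   logit(pr(case)) = b0 + stratum offset + b_size * size_kb
#                     + b_total * n_genes_total + sum_s beta_s * hits_s
# so embedded set effects (odds ratios) are known truth for recovery tests.
# Covariates are computed by the package's own annotation code.

#' Simulation configuration
#'
#' Builds the configuration list consumed by the generators, with defaults
#' sized for a desk-scale case-control CNV study: three study-by-chip strata
#' totalling 4,000 CNVs (about 44% from cases), a 200 Mb / 4-chromosome
#' genome carrying 1,500 non-overlapping genes, a 3 kb probe grid, and a
#' battery of 134 overlapping gene sets. CNV lengths are log-normal per
#' copy-state (deletions smaller than duplications, all at least 100 kb), and
#' 40% of CNVs are deletions.
#'
#' @param ... Overrides for any default field. Fields: `chrom_lengths` (named
#'   vector, bp), `n_genes`, `gene_meanlog`/`gene_sdlog` (log-normal gene
#'   lengths, bp), `probe_spacing` (bp), `lcr_frac`/`lcr_mean_len`, `n_sets`,
#'   `set_size_range` (log-uniform), `target_jaccard` (expected pairwise
#'   Jaccard overlap of sets; `NULL` = uniform sampling), `pool_size`,
#'   `strata` (tibble with `study`, `chip`, `n_cnv`, `offset`), `del_frac`,
#'   `len_meanlog`/`len_sdlog` (named by copy-state), `min_cnv_len`, `b0`,
#'   `b_size` (per kb), `b_total` (per gene), `beta_sets` (named vector of
#'   per-set log-odds per set gene hit), `per_individual`,
#'   `cnvs_per_sample`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    chrom_lengths = setNames(rep(50e6, 4), paste0("chr", 1:4)),
    n_genes = 1500,
    gene_meanlog = log(3e4), gene_sdlog = 0.8,
    probe_spacing = 3000,
    lcr_frac = 0.03, lcr_mean_len = 5e4,
    n_sets = 134,
    set_size_range = c(10, 150),
    target_jaccard = NULL,
    pool_size = 200,
    strata = tibble(
      study = c("CLOZUK", "MGS", "ISC"),
      chip = c("Illumina", "Affy6", "Affy5"),
      n_cnv = c(2000L, 1000L, 1000L),
      offset = c(0, 0.05, -0.05)
    ),
    del_frac = 0.4,
    len_meanlog = c(del = log(1.8e5), dup = log(2.5e5)),
    len_sdlog = c(del = 0.5, dup = 0.5),
    min_cnv_len = 1e5,
    b0 = -0.35,
    b_size = 2e-4,
    b_total = 0.02,
    beta_sets = numeric(0),
    per_individual = FALSE,
    cnvs_per_sample = 1.3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config field(s): ", paste(unknown, collapse = ", ")))
  }
  for (i in seq_along(over)) cfg[[names(over)[i]]] <- over[[i]] # wholesale
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome
#'
#' Places non-overlapping genes uniformly along each chromosome (gene counts
#' proportional to chromosome length, log-normal lengths), lays probes on a
#' regular grid with uniform jitter, and scatters low-copy-repeat intervals
#' covering about `lcr_frac` of each chromosome.
#'
#' @param cfg A [sim_config()] list.
#' @param seed Integer seed.
#' @return A list with `genes`, `probes` and `lcr` tibbles in the package's
#'   standard layouts.
#' @export
simulate_genome <- function(cfg, seed = 1) {
  set.seed(seed)
  chroms <- names(cfg$chrom_lengths)
  n_per <- round(cfg$n_genes * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  genes <- list(); probes <- list(); lcr <- list()
  gid <- 0L
  for (chr in chroms) {
    L <- cfg$chrom_lengths[[chr]]
    n <- n_per[[chr]]
    len <- round(rlnorm(n, cfg$gene_meanlog, cfg$gene_sdlog))
    len <- pmax(len, 200)
    if (sum(len) >= L) {
      abort(paste0("genes cannot fit on ", chr,
        ": total gene length exceeds chromosome length"))
    }
    slack <- L - sum(len)
    gaps <- stats::rexp(n + 1)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
    genes[[chr]] <- tibble(
      gene_id = sprintf("G%04d", gid + seq_len(n)),
      chrom = chr, start = starts, end = starts + len
    )
    gid <- gid + n
    pos <- seq(0, L - cfg$probe_spacing, by = cfg$probe_spacing) +
      round(runif(length(seq(0, L - cfg$probe_spacing, by = cfg$probe_spacing)),
        0, cfg$probe_spacing / 3))
    probes[[chr]] <- tibble(chrom = chr, pos = sort(unique(pos)))
    n_lcr <- max(1, round(cfg$lcr_frac * L / cfg$lcr_mean_len))
    ls <- round(runif(n_lcr, 0, L - cfg$lcr_mean_len * 2))
    ll <- round(rlnorm(n_lcr, log(cfg$lcr_mean_len), 0.5))
    lcr[[chr]] <- tibble(chrom = chr, start = ls, end = pmin(ls + ll, L))
  }
  list(
    genes = bind_rows(genes),
    probes = bind_rows(probes),
    lcr = normalize_regions(bind_rows(lcr))
  )
}

#' Generate an overlapping gene-set battery
#'
#' Samples `n_sets` sets with log-uniform sizes in `set_size_range`. With
#' `target_jaccard = NULL` members are drawn uniformly; otherwise each set
#' draws a fraction of members from a small shared pool of `pool_size` genes,
#' the fraction solved so the expected pairwise Jaccard overlap matches the
#' target.
#'
#' @param cfg A [sim_config()] list.
#' @param genes Gene tibble from [simulate_genome()].
#' @param seed Integer seed.
#' @return A named list of gene-id vectors.
#' @export
simulate_gene_sets <- function(cfg, genes, seed = 1) {
  set.seed(seed)
  if (cfg$n_sets == 0) return(setNames(list(), character(0)))
  N <- nrow(genes)
  lo <- cfg$set_size_range[1]; hi <- cfg$set_size_range[2]
  if (hi > N) abort("set sizes exceed the number of genes")
  sizes <- round(exp(runif(cfg$n_sets, log(lo), log(hi))))
  pool_frac <- 0
  pool <- character(0)
  if (!is.null(cfg$target_jaccard)) {
    P <- cfg$pool_size
    m <- exp(mean(log(sizes)))
    jac <- function(f) {
      inter <- (f * m)^2 / P + ((1 - f) * m)^2 / (N - P)
      inter / (2 * m - inter)
    }
    if (cfg$target_jaccard < jac(0) || cfg$target_jaccard > jac(1)) {
      abort(paste0("target_jaccard must lie in [", signif(jac(0), 3), ", ",
        signif(jac(1), 3), "] for this configuration"))
    }
    pool_frac <- uniroot(function(f) jac(f) - cfg$target_jaccard, c(0, 1))$root
    pool <- sample(genes$gene_id, P)
  }
  sets <- map(sizes, function(m) {
    k <- rbinom(1, m, pool_frac)
    k <- min(k, length(pool))
    members <- c(
      if (k > 0) sample(pool, k) else character(0),
      sample(setdiff(genes$gene_id, pool), m - k)
    )
    unique(members)
  })
  setNames(sets, sprintf("SET%03d", seq_len(cfg$n_sets)))
}

#' Simulate a case-control CNV dataset with known set effects
#'
#' Draws CNV positions, lengths and copy-states per stratum, annotates them
#' with the package's own annotation code, and assigns each CNV's
#' case-control label from the logistic model with the configured baseline,
#' size, total-genes and per-set coefficients. Per-stratum case/control
#' totals are realized, not forced. With `per_individual = TRUE`, CNVs are
#' grouped into samples and each sample's CNVs share one label drawn from
#' the sample-mean linear predictor.
#'
#' @param cfg A [sim_config()] list.
#' @param genes Gene tibble.
#' @param sets Named list of gene sets (needed when `beta_sets` is
#'   non-empty).
#' @param seed Integer seed.
#' @return A list: `cnvs` (annotated CNV tibble) and `truth` (list with the
#'   seed, per-set true betas and the per-CNV linear predictor).
#' @export
simulate_cnvs <- function(cfg, genes, sets = list(), seed = 1) {
  set.seed(seed)
  chroms <- names(cfg$chrom_lengths)
  chr_p <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  out <- list()
  for (i in seq_len(nrow(cfg$strata))) {
    st <- cfg$strata[i, ]
    n <- st$n_cnv
    state <- ifelse(runif(n) < cfg$del_frac, "del", "dup")
    len <- round(rlnorm(n, cfg$len_meanlog[state], cfg$len_sdlog[state]))
    redraw <- which(len < cfg$min_cnv_len)
    while (length(redraw) > 0) {
      len[redraw] <- round(rlnorm(length(redraw),
        cfg$len_meanlog[state[redraw]], cfg$len_sdlog[state[redraw]]))
      redraw <- redraw[len[redraw] < cfg$min_cnv_len]
    }
    chrom <- sample(chroms, n, replace = TRUE, prob = chr_p)
    maxlen <- cfg$chrom_lengths[chrom]
    len <- pmin(len, floor(maxlen / 2))
    start <- floor(runif(n) * (maxlen - len))
    out[[i]] <- tibble(
      sample_id = NA_character_,
      chrom = chrom, start = start, end = start + len,
      copy_state = state,
      n_probes = as.integer(round(len / cfg$probe_spacing)),
      study = st$study, chip = st$chip,
      phenotype = NA_integer_,
      offset = st$offset
    )
  }
  cnvs <- bind_rows(out)
  n_all <- nrow(cnvs)
  if (cfg$per_individual) {
    n_samp <- ceiling(n_all / cfg$cnvs_per_sample)
    cnvs$sample_id <- sprintf("S%05d", sample.int(n_samp, n_all, replace = TRUE))
    # one individual belongs to one stratum: re-key by stratum
    cnvs$sample_id <- paste0(cnvs$study, ":", cnvs$sample_id)
  } else {
    cnvs$sample_id <- sprintf("S%05d", seq_len(n_all))
  }
  offset <- cnvs$offset
  cnvs$offset <- NULL
  cnvs$phenotype <- 0L # placeholder for validation inside annotate_cnvs
  cnvs <- annotate_cnvs(cnvs, genes)
  beta <- cfg$beta_sets
  missing <- setdiff(names(beta), names(sets))
  if (length(missing) > 0) {
    abort(paste0("beta_sets refers to unknown set(s): ",
      paste(missing, collapse = ", ")))
  }
  lp <- cfg$b0 + offset + cfg$b_size * cnvs$size_kb +
    cfg$b_total * cnvs$n_genes_total
  for (nm in names(beta)) {
    lp <- lp + beta[[nm]] * set_hit_count(cnvs, sets[[nm]])
  }
  if (cfg$per_individual) {
    lp_samp <- tapply(lp, cnvs$sample_id, mean)
    y_samp <- rbinom(length(lp_samp), 1, plogis(lp_samp))
    names(y_samp) <- names(lp_samp)
    cnvs$phenotype <- as.integer(y_samp[cnvs$sample_id])
  } else {
    cnvs$phenotype <- rbinom(n_all, 1, plogis(lp))
  }
  list(
    cnvs = cnvs,
    truth = list(seed = seed, beta_sets = beta, b0 = cfg$b0,
      b_size = cfg$b_size, b_total = cfg$b_total, linear_predictor = lp)
  )
}

#' Simulate a complete study
#'
#' Convenience wrapper: genome, gene-set battery and CNV dataset from one
#' configuration and seed (sub-seeds are derived deterministically).
#'
#' @param cfg A [sim_config()] list.
#' @param seed Integer master seed.
#' @return A list: `genes`, `probes`, `lcr`, `sets`, `cnvs`, `truth`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  seeds <- derive_seeds(seed, 3)
  genome <- simulate_genome(cfg, seeds[1])
  sets <- simulate_gene_sets(cfg, genome$genes, seeds[2])
  sim <- simulate_cnvs(cfg, genome$genes, sets, seeds[3])
  c(genome, list(sets = sets), sim)
}
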