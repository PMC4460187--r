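# End-to-end orchestration: QC -> annotation -> per-analysis enrichment ->
# permutation excess -> minimal set -> burden -> top genes, from one config.

#' Pipeline configuration
#'
#' Assembles the configuration for [run_cnv_pipeline()]. Inputs may be file
#' paths (TSV/BED/GMT, read with the package readers) or in-memory objects in
#' the package's standard layouts.
#'
#' @param cnvs CNV table (path or tibble).
#' @param genes Gene table (path or tibble).
#' @param sets Gene sets (GMT path or named list).
#' @param probes Probe map (path or tibble), or `NULL`.
#' @param lcr Low-copy-repeat regions (path or tibble), or `NULL`.
#' @param known_loci Known risk loci (path or tibble), or `NULL`; when given,
#'   the enrichment battery is re-run after removing CNVs overlapping them.
#' @param coords Coordinate dialect of the CNV input (`"bed"` or `"1based"`).
#' @param n_samples Total genotyped samples for the frequency filter
#'   (default: number of distinct sample ids).
#' @param analyses Analyses to run, subset of `c("combined", "del", "dup")`.
#' @param n_tests Bonferroni factor for the battery (default: sets x
#'   analyses).
#' @param qc Named list of QC threshold overrides passed to [cnv_qc()].
#' @param run_qc Apply QC (set `FALSE` when `cnvs` is already analysis-ready).
#' @param permutation `NULL` to skip, or a list with `n_perm` and
#'   `thresholds`.
#' @param alpha_adj Adjusted-p threshold used for the minimal-set candidate
#'   list, the union burden set and top-gene extraction.
#' @param seed Integer seed for the permutation test.
#' @param out_dir Output directory for TSVs, report and log; `NULL` writes
#'   nothing.
#' @return A list of class `cnv_run_config`.
#' @export
pipeline_config <- function(cnvs, genes, sets, probes = NULL, lcr = NULL,
                            known_loci = NULL, coords = "bed",
                            n_samples = NULL,
                            analyses = c("combined", "del", "dup"),
                            n_tests = NULL, qc = list(), run_qc = TRUE,
                            permutation = list(n_perm = 1000,
                              thresholds = c(0.01, 0.001)),
                            alpha_adj = 0.05, seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "cnv_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [pipeline_config()]
#' (file-path inputs only).
#'
#' @param path Path to the YAML file.
#' @return A `cnv_run_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

resolve_input <- function(x, reader, ...) {
  if (is.null(x) || !is.character(x) || length(x) != 1) return(x)
  reader(x, ...)
}

#' Run the full CNV enrichment pipeline
#'
#' Applies quality control, annotates CNVs with genes, tests the gene-set
#' battery under each requested analysis (Bonferroni-corrected across the
#' battery and analyses), runs the within-stratum permutation excess test,
#' selects the minimal explanatory set, performs burden analyses (size,
#' total genes hit, and genes hit in the union of associated sets), extracts
#' top genes from associated sets, and — when known loci are supplied —
#' repeats the battery after removing CNVs overlapping them. Deterministic
#' given the seed.
#'
#' @param config A `cnv_run_config` list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @return A list of result tables: `cnvs` (analysis-ready), `enrichment`,
#'   `excess`, `minimal_set` (per analysis), `burden`, `top_genes`,
#'   `enrichment_minus_loci` (when loci given). Written as TSVs plus a
#'   rounded human-readable report and a run log when `out_dir` is set.
#' @export
run_cnv_pipeline <- function(config) {
  cfg <- config
  log_lines <- c(
    paste0("cnvenrich ", as.character(utils::packageVersion("cnvenrich")),
      " | R ", R.version.string),
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", cfg$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  cnvs <- stage("read_cnvs", resolve_input(cfg$cnvs, read_cnv_table,
    coords = cfg$coords))
  genes <- stage("read_genes", resolve_input(cfg$genes, read_gene_table))
  sets <- stage("read_sets", resolve_input(cfg$sets, read_gmt))
  probes <- stage("read_probes", resolve_input(cfg$probes, read_probe_map))
  lcr <- stage("read_lcr", resolve_input(cfg$lcr, read_regions_bed))
  loci <- stage("read_loci", resolve_input(cfg$known_loci, read_regions_bed))
  n_samples <- cfg$n_samples %||% dplyr::n_distinct(cnvs$sample_id)

  if (isTRUE(cfg$run_qc)) {
    qc_args <- c(list(cnvs = cnvs, lcr = lcr, probes = probes,
      n_samples = n_samples), cfg$qc)
    cnvs <- stage("qc", do.call(cnv_qc, qc_args))
    log_lines <- c(log_lines, paste0("QC: ", nrow(cnvs), " CNVs retained"))
  }
  ann <- if (all(c("size_kb", "genes_hit", "n_genes_total") %in% names(cnvs))) {
    cnvs
  } else {
    stage("annotate", annotate_cnvs(cnvs, genes))
  }

  n_tests <- cfg$n_tests %||% (length(sets) * length(cfg$analyses))
  log_lines <- c(log_lines,
    paste0("battery: ", length(sets), " sets x ", length(cfg$analyses),
      " analyses; Bonferroni n_tests = ", n_tests))

  enr <- stage("enrichment", bind_rows(map(cfg$analyses, function(a) {
    set_enrichment_test(ann, sets, analysis = a, n_tests = n_tests)
  })))

  excess <- NULL
  if (!is.null(cfg$permutation)) {
    excess <- stage("permutation", bind_rows(map(cfg$analyses, function(a) {
      mutate(excess_enrichment_test(filter_analysis(ann, a), sets,
        thresholds = cfg$permutation$thresholds,
        n_perm = cfg$permutation$n_perm, seed = cfg$seed,
        n_comparisons = length(cfg$permutation$thresholds) *
          length(cfg$analyses)),
        analysis = a, .before = 1)
    })))
  }

  minimal <- stage("minimal_set", map(setNames(cfg$analyses, cfg$analyses),
    function(a) {
      pass <- filter(enr, .data$analysis == a, .data$p_adj < cfg$alpha_adj)
      minimal_set_selection(ann, sets[pass$set_name], analysis = a)
    }))

  burden <- stage("burden", bind_rows(map(cfg$analyses, function(a) {
    pass <- filter(enr, .data$analysis == a, .data$p_adj < cfg$alpha_adj)
    base <- bind_rows(
      burden_analysis(ann, c("size", "n_genes_total"), analysis = a),
      burden_analysis(ann, "n_genes_total", conditioning = "size",
        analysis = a),
      burden_analysis(ann, "size", conditioning = "n_genes_total",
        analysis = a)
    )
    if (nrow(pass) > 0) {
      u <- build_union_set(pass, sets)[[1]]
      base <- bind_rows(base,
        burden_analysis(ann, "n_genes_set", burden_set = u, analysis = a),
        burden_analysis(ann, "n_genes_set", conditioning = "n_genes_total",
          burden_set = u, analysis = a),
        burden_analysis(ann, "n_genes_total", conditioning = "n_genes_set",
          burden_set = u, analysis = a)
      )
    }
    base
  })))

  top_genes <- stage("top_genes", bind_rows(map(cfg$analyses, function(a) {
    res <- filter(enr, .data$analysis == a)
    tg <- extract_top_genes(res, ann, sets, alpha_adj = cfg$alpha_adj)
    if (nrow(tg) > 0) mutate(tg, analysis = a, .before = 1) else NULL
  })))

  enr_minus <- NULL
  if (!is.null(loci)) {
    kept <- stage("remove_known_loci", remove_known_loci(ann, loci))
    enr_minus <- stage("enrichment_minus_loci",
      bind_rows(map(cfg$analyses, function(a) {
        set_enrichment_test(kept, sets, analysis = a, n_tests = n_tests)
      })))
    log_lines <- c(log_lines, paste0("known-locus removal: ", nrow(kept),
      " of ", nrow(ann), " CNVs retained"))
  }

  out <- list(cnvs = ann, enrichment = enr, excess = excess,
    minimal_set = minimal, burden = burden, top_genes = top_genes,
    enrichment_minus_loci = enr_minus, log = log_lines)

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  invisible(out)
}

# machine TSVs keep full precision; report.txt is rounded for reading
write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cnv_table(out$cnvs, file.path(dir, "cnvs_analysis_ready.tsv"))
  readr::write_tsv(out$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(out$excess)) {
    readr::write_tsv(out$excess, file.path(dir, "excess_permutation.tsv"))
  }
  ms <- bind_rows(map(names(out$minimal_set), function(a) {
    mutate(out$minimal_set[[a]]$steps, analysis = a, .before = 1)
  }))
  readr::write_tsv(ms, file.path(dir, "minimal_set_steps.tsv"))
  sel <- bind_rows(map(names(out$minimal_set), function(a) {
    s <- out$minimal_set[[a]]$selected
    tibble(analysis = a, rank = seq_along(s), set_name = s)
  }))
  readr::write_tsv(sel, file.path(dir, "minimal_set_selected.tsv"))
  readr::write_tsv(out$burden, file.path(dir, "burden.tsv"))
  readr::write_tsv(out$top_genes, file.path(dir, "top_genes.tsv"))
  if (!is.null(out$enrichment_minus_loci)) {
    readr::write_tsv(out$enrichment_minus_loci,
      file.path(dir, "enrichment_minus_known_loci.tsv"))
  }
  rounded <- mutate(out$enrichment,
    p_one_sided = signif(.data$p_one_sided, 2),
    p_adj = signif(.data$p_adj, 2),
    odds_ratio = round(.data$odds_ratio, 2),
    ci_lo = round(.data$ci_lo, 2), ci_hi = round(.data$ci_hi, 2),
    delta_deviance = round(.data$delta_deviance, 2),
    beta_set = round(.data$beta_set, 3)
  )
  readr::write_tsv(rounded, file.path(dir, "report_enrichment.tsv"))
  if (!is.null(out$excess)) {
    readr::write_tsv(
      mutate(out$excess, n_exp = round(.data$n_exp, 1)),
      file.path(dir, "report_excess.tsv")
    )
  }
  readr::write_lines(out$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
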