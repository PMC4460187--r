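# Fixture constructors. All coordinates 0-based half-open.

cnv_tbl <- function(start, end, sample_id = "S1", chrom = "chr1",
                    copy_state = "del", n_probes = 20L, study = "A",
                    chip = "X", phenotype = 0L) {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, start = start, end = end,
    copy_state = copy_state, n_probes = as.integer(n_probes),
    study = study, chip = chip, phenotype = as.integer(phenotype)
  )
}

regions_tbl <- function(start, end, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

# annotated rows built directly (no gene table needed): genes_hit is a list
# of character vectors
ann_tbl <- function(genes_hit, phenotype, size_kb = 100, study = "A",
                    chip = "X", copy_state = "del", chrom = "chr1") {
  n <- length(genes_hit)
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    chrom = chrom, start = 0, end = size_kb * 1000,
    copy_state = copy_state, n_probes = 30L,
    study = study, chip = chip, phenotype = as.integer(phenotype),
    size_kb = size_kb, genes_hit = genes_hit,
    n_genes_total = lengths(genes_hit)
  )
}

# random raw CNV table for property checks
random_cnvs <- function(n, n_samples = 5, chroms = c("chr1", "chr2"),
                        max_pos = 1e6, min_len = 1000, max_len = 50000) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  sid <- sample(sprintf("S%02d", seq_len(n_samples)), n, replace = TRUE)
  pheno <- as.integer(substr(sid, 2, 3)) %% 2L # phenotype constant per sample
  cnv_tbl(
    start = start, end = start + len,
    sample_id = sid,
    chrom = sample(chroms, n, replace = TRUE),
    copy_state = sample(c("del", "dup"), n, replace = TRUE),
    n_probes = sample(15:60, n, replace = TRUE),
    phenotype = pheno
  )
}

# small annotated case-control dataset where set hits are assigned directly:
# h_case / h_ctrl give per-CNV counts of hit set-member genes; every CNV is
# padded with non-member genes to the same total so n_genes_total is constant
# (the "equal sizes and total-gene counts" situation)
balanced_ann <- function(h_case, h_ctrl, set_genes = paste0("m", 1:20),
                         other_genes = paste0("o", 1:20)) {
  total <- max(c(h_case, h_ctrl)) + 2
  mk <- function(h) lapply(h, function(k) {
    c(if (k > 0) set_genes[seq_len(k)] else character(0),
      other_genes[seq_len(total - k)])
  })
  ann_tbl(
    genes_hit = c(mk(h_case), mk(h_ctrl)),
    phenotype = c(rep(1L, length(h_case)), rep(0L, length(h_ctrl)))
  )
}
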