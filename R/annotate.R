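# Gene annotation of QC-passing CNVs and gene-set hit counting.

# per-chromosome IRanges index of gene spans
gene_index <- function(genes) {
  split(genes, genes$chrom)
}

#' Genes hit by a single CNV span
#'
#' A gene is counted as hit when the CNV overlaps any part of its span by at
#' least one base (half-open coordinates: a gene starting exactly at the CNV
#' end is not hit).
#'
#' @param chrom,start,end CNV span (0-based half-open).
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Character vector of gene ids.
#' @export
genes_hit_by_cnv <- function(chrom, start, end, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(character(0))
  hit <- IRanges::overlapsAny(as_iranges0(g$start, g$end),
    as_iranges0(start, end))
  g$gene_id[hit]
}

#' Annotate CNVs with the genes they hit
#'
#' Adds `size_kb` (length in kilobases), `genes_hit` (list-column of gene
#' ids overlapped by at least one base) and `n_genes_total` to a QC-passing
#' CNV table. CNVs hitting no genes are kept: gene deserts stay in the
#' regression with a zero gene count.
#'
#' @param cnvs CNV tibble.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Annotated CNV tibble, input order preserved.
#' @export
annotate_cnvs <- function(cnvs, genes) {
  validate_cnvs(cnvs)
  hits <- vector("list", nrow(cnvs))
  for (chr in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == chr)
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) {
      hits[ci] <- list(character(0))
      next
    }
    ov <- IRanges::findOverlaps(as_iranges0(cnvs$start[ci], cnvs$end[ci]),
      as_iranges0(g$start, g$end))
    found <- split(g$gene_id[S4Vectors::subjectHits(ov)],
      factor(S4Vectors::queryHits(ov), levels = seq_along(ci)))
    hits[ci] <- unname(found)
  }
  mutate(cnvs,
    size_kb = (.data$end - .data$start) / 1000,
    genes_hit = hits,
    n_genes_total = lengths(hits)
  )
}

#' Per-CNV count of genes hit within a gene set
#'
#' Counts how many of a CNV's hit genes belong to the set. A CNV hitting k
#' set members contributes a covariate value of k in the enrichment model —
#' one row per CNV, never one row per gene, so co-localized set members do
#' not inflate set-level significance.
#'
#' @param cnvs Annotated CNV tibble.
#' @param set Character vector of gene ids.
#' @return Integer vector, one count per CNV row.
#' @export
set_hit_count <- function(cnvs, set) {
  validate_cnvs(cnvs, annotated = TRUE)
  map_int(cnvs$genes_hit, function(g) length(intersect(g, set)))
}

# n_cnv x n_set sparse matrix of set hit counts, used by the batch tests
hit_count_matrix <- function(cnvs, sets) {
  validate_cnvs(cnvs, annotated = TRUE)
  validate_sets(sets)
  universe <- unique(c(unlist(cnvs$genes_hit, use.names = FALSE),
    unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    return(matrix(0L, nrow(cnvs), length(sets),
      dimnames = list(NULL, names(sets))))
  }
  gh <- unlist(cnvs$genes_hit, use.names = FALSE)
  inc <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(cnvs)), lengths(cnvs$genes_hit)),
    j = match(gh, universe), x = 1,
    dims = c(nrow(cnvs), length(universe))
  )
  mem <- Matrix::sparseMatrix(
    i = match(unlist(sets, use.names = FALSE), universe),
    j = rep(seq_along(sets), lengths(sets)), x = 1,
    dims = c(length(universe), length(sets))
  )
  out <- as.matrix(inc %*% mem)
  dimnames(out) <- list(NULL, names(sets))
  out
}

#' Union of gene sets surviving multiple-testing correction
#'
#' Builds the combined "associated" set (e.g. CNS_SZ) from all sets whose
#' adjusted p value passes `alpha_adj` in an enrichment result table, for use
#' as a burden predictor.
#'
#' @param results Enrichment result tibble (see [set_enrichment_test()]).
#' @param sets Named list of gene sets the results refer to.
#' @param alpha_adj Adjusted-p threshold for inclusion (default 0.05).
#' @param name Name for the union set (default `CNS_SZ_<analysis>`).
#' @return A named list of length one: the union set.
#' @export
build_union_set <- function(results, sets, alpha_adj = 0.05, name = NULL) {
  validate_sets(sets)
  pass <- results$set_name[results$p_adj < alpha_adj]
  if (length(pass) == 0) {
    abort("no set passes alpha_adj; supply an explicit set list instead")
  }
  missing <- setdiff(pass, names(sets))
  if (length(missing) > 0) {
    abort(paste0("passing sets absent from `sets`: ",
      paste(missing, collapse = ", ")))
  }
  if (is.null(name)) {
    analysis <- unique(results$analysis[results$set_name %in% pass])
    name <- paste0("CNS_SZ_", paste(analysis, collapse = "_"))
  }
  setNames(list(unique(unlist(sets[pass], use.names = FALSE))), name)
}
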