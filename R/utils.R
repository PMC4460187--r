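# Shared validation and interval helpers. Coordinates are 0-based, half-open
# [start, end) throughout the package; IRanges (1-based, closed) is used only
# transiently inside overlap computations.

cnv_required_cols <- c(
  "sample_id", "chrom", "start", "end", "copy_state",
  "n_probes", "study", "chip", "phenotype"
)

validate_cnvs <- function(cnvs, annotated = FALSE, call = rlang::caller_env()) {
  missing <- setdiff(cnv_required_cols, names(cnvs))
  if (length(missing) > 0) {
    abort(paste0("CNV table is missing columns: ", paste(missing, collapse = ", ")),
      call = call)
  }
  if (any(cnvs$end <= cnvs$start)) {
    abort("CNV table contains intervals with end <= start", call = call)
  }
  if (!all(cnvs$copy_state %in% c("del", "dup"))) {
    abort("copy_state must be 'del' or 'dup'", call = call)
  }
  if (!all(cnvs$phenotype %in% c(0L, 1L))) {
    abort("phenotype must be 0 (control) or 1 (case)", call = call)
  }
  if (annotated && !all(c("size_kb", "genes_hit", "n_genes_total") %in% names(cnvs))) {
    abort("expected an annotated CNV table; run annotate_cnvs() first", call = call)
  }
  invisible(cnvs)
}

validate_regions <- function(regions, call = rlang::caller_env()) {
  missing <- setdiff(c("chrom", "start", "end"), names(regions))
  if (length(missing) > 0) {
    abort(paste0("region table is missing columns: ", paste(missing, collapse = ", ")),
      call = call)
  }
  if (any(regions$end <= regions$start)) {
    abort("region table contains intervals with end <= start", call = call)
  }
  invisible(regions)
}

validate_sets <- function(sets, call = rlang::caller_env()) {
  if (!is.list(sets) || (length(sets) > 0 && is.null(names(sets)))) {
    abort("gene sets must be a named list of character vectors", call = call)
  }
  if (anyDuplicated(names(sets))) {
    abort("duplicate gene set names", call = call)
  }
  invisible(sets)
}

# normalize a region table: sorted within chromosome
normalize_regions <- function(regions) {
  validate_regions(regions)
  dplyr::arrange(as_tibble(regions), .data$chrom, .data$start, .data$end)
}

# half-open [start, end) -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# per-call total bp covered by the union of regions on the same chromosome
overlap_bp <- function(cnvs, regions) {
  out <- numeric(nrow(cnvs))
  for (chr in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == chr)
    ri <- which(regions$chrom == chr)
    if (length(ri) == 0) next
    q <- as_iranges0(cnvs$start[ci], cnvs$end[ci])
    s <- IRanges::reduce(as_iranges0(regions$start[ri], regions$end[ri]))
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]
    ))
    out[ci] <- out[ci] + as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
      levels = seq_along(ci)), sum, default = 0))
  }
  out
}

# TRUE for calls overlapping any region by >= 1 bp
overlaps_any <- function(cnvs, regions) {
  out <- logical(nrow(cnvs))
  for (chr in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == chr)
    ri <- which(regions$chrom == chr)
    if (length(ri) == 0) next
    q <- as_iranges0(cnvs$start[ci], cnvs$end[ci])
    s <- as_iranges0(regions$start[ri], regions$end[ri])
    out[ci] <- IRanges::overlapsAny(q, s)
  }
  out
}

stratum_of <- function(cnvs) {
  interaction(cnvs$study, cnvs$chip, drop = TRUE, sep = ":")
}

# deterministic per-task substream seeds derived from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
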