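# Post-calling CNV quality control.
#
# All operations take and return a CNV tibble (see read_cnv_table()) and are
# pure filters apart from merge_adjacent(), which replaces groups of fragments
# with their merged span. Filters keep input row order.

#' Join CNV fragments separated by small gaps
#'
#' Within each (sample, chromosome, copy-state) group, two calls are joined
#' when the gap separating them is smaller than half their combined length.
#' Joining is iterated to a fixpoint: the merged span can in turn absorb
#' further neighbours. A merged call spans from the smallest start to the
#' largest end of its members and carries the summed probe count.
#'
#' @param cnvs CNV tibble.
#' @return CNV tibble with fragmented calls replaced by their merged spans,
#'   sorted by sample, chromosome, copy-state and start.
#' @export
merge_adjacent <- function(cnvs) {
  validate_cnvs(cnvs)
  conflict <- cnvs |>
    group_by(.data$sample_id) |>
    summarise(bad = dplyr::n_distinct(.data$phenotype) > 1 |
      dplyr::n_distinct(.data$study) > 1 | dplyr::n_distinct(.data$chip) > 1)
  if (any(conflict$bad)) {
    abort(paste0("conflicting phenotype/study/chip within sample(s): ",
      paste(conflict$sample_id[conflict$bad], collapse = ", ")))
  }
  cnvs |>
    group_by(.data$sample_id, .data$chrom, .data$copy_state) |>
    dplyr::group_modify(~ merge_group(.x)) |>
    ungroup() |>
    dplyr::relocate(all_of(cnv_required_cols)) |>
    arrange(.data$sample_id, .data$chrom, .data$copy_state, .data$start)
}

# left-to-right scan over start-sorted calls, repeated until no pair merges
merge_group <- function(g) {
  g <- arrange(g, .data$start, .data$end)
  repeat {
    if (nrow(g) < 2) return(g)
    merged_any <- FALSE
    out <- g[1, , drop = FALSE]
    for (i in 2:nrow(g)) {
      cur <- out[nrow(out), ]
      nxt <- g[i, ]
      gap <- nxt$start - cur$end
      if (gap < 0.5 * ((cur$end - cur$start) + (nxt$end - nxt$start))) {
        out$start[nrow(out)] <- min(cur$start, nxt$start)
        out$end[nrow(out)] <- max(cur$end, nxt$end)
        out$n_probes[nrow(out)] <- cur$n_probes + nxt$n_probes
        merged_any <- TRUE
      } else {
        out <- bind_rows(out, nxt)
      }
    }
    g <- out
    if (!merged_any) return(g)
  }
}

#' Remove CNVs lying mostly in low-copy repeats
#'
#' A call is removed when the union of low-copy-repeat (LCR) intervals covers
#' strictly more than `max_overlap_frac` of its length. LCR regions are prone
#' to artifactual calls on SNP arrays.
#'
#' @param cnvs CNV tibble.
#' @param lcr Region tibble (`chrom`, `start`, `end`) of LCR intervals.
#' @param max_overlap_frac Maximum tolerated covered fraction (default 0.5).
#' @return Filtered CNV tibble (row order preserved).
#' @export
filter_lcr <- function(cnvs, lcr, max_overlap_frac = 0.5) {
  validate_cnvs(cnvs)
  lcr <- normalize_regions(lcr)
  cov <- overlap_bp(cnvs, lcr)
  keep <- cov / (cnvs$end - cnvs$start) <= max_overlap_frac
  cnvs[keep, , drop = FALSE]
}

#' Remove CNVs with low probe support density
#'
#' A call is removed when the number of array probes falling inside its span,
#' divided by its length, is below `min_density` (default 1 probe / 20 kb).
#' Density is computed from the probe map, not from the stored `n_probes`
#' (post-merge probe sums can double-count). With `probes = NULL` the function
#' falls back to `n_probes / length` with a warning.
#'
#' @param cnvs CNV tibble.
#' @param probes Probe map tibble (`chrom`, `pos`) or `NULL`.
#' @param min_density Minimum probes per bp (default `1 / 20000`).
#' @return Filtered CNV tibble (row order preserved).
#' @export
filter_probe_density <- function(cnvs, probes = NULL, min_density = 1 / 20000) {
  validate_cnvs(cnvs)
  len <- cnvs$end - cnvs$start
  if (is.null(probes)) {
    warn("no probe map supplied; falling back to stored n_probes for density")
    n_in <- cnvs$n_probes
  } else {
    missing_chr <- setdiff(unique(cnvs$chrom), unique(probes$chrom))
    if (length(missing_chr) > 0) {
      abort(paste0("probe map has no probes for chromosome(s): ",
        paste(missing_chr, collapse = ", ")))
    }
    n_in <- count_probes(cnvs, probes)
  }
  keep <- n_in / len >= min_density
  cnvs[keep, , drop = FALSE]
}

# probes p with start <= p < end, via binary search on the sorted per-chrom map
count_probes <- function(cnvs, probes) {
  out <- integer(nrow(cnvs))
  for (chr in unique(cnvs$chrom)) {
    ci <- which(cnvs$chrom == chr)
    pos <- sort(probes$pos[probes$chrom == chr])
    out[ci] <- findInterval(cnvs$end[ci] - 1, pos) -
      findInterval(cnvs$start[ci] - 1, pos)
  }
  out
}

#' Remove small or poorly supported CNVs
#'
#' Retains calls with length at least `min_len` and probe count at least
#' `min_probes` (both thresholds inclusive); the analysis is restricted to
#' large, well-supported CNVs.
#'
#' @param cnvs CNV tibble.
#' @param min_len Minimum length in bp (default 100000).
#' @param min_probes Minimum supporting probe count (default 15).
#' @return Filtered CNV tibble (row order preserved).
#' @export
filter_size_probes <- function(cnvs, min_len = 1e5, min_probes = 15) {
  validate_cnvs(cnvs)
  keep <- (cnvs$end - cnvs$start) >= min_len & cnvs$n_probes >= min_probes
  cnvs[keep, , drop = FALSE]
}

#' Remove common CNVs
#'
#' Calls of the same copy-state are clustered by single linkage, linking any
#' two calls with at least `recip_overlap` reciprocal overlap (each covered by
#' the other to that fraction). A call is removed when the number of distinct
#' carriers in its cluster exceeds `max_freq` of the total genotyped sample.
#'
#' @param cnvs CNV tibble.
#' @param n_samples Total number of genotyped samples (cases + controls) in
#'   the collated dataset; must be at least the number of distinct sample ids.
#' @param max_freq Maximum tolerated carrier frequency (default 0.01).
#' @param recip_overlap Reciprocal overlap fraction defining "the same CNV"
#'   (default 0.5).
#' @return Filtered CNV tibble (row order preserved).
#' @export
filter_frequency <- function(cnvs, n_samples, max_freq = 0.01,
                             recip_overlap = 0.5) {
  validate_cnvs(cnvs)
  if (n_samples < dplyr::n_distinct(cnvs$sample_id)) {
    abort("n_samples is smaller than the number of distinct sample_ids")
  }
  cl <- overlap_clusters(cnvs, recip_overlap)
  carriers <- tapply(cnvs$sample_id, cl, function(s) length(unique(s)))
  keep <- as.numeric(carriers[as.character(cl)]) / n_samples <= max_freq
  cnvs[keep, , drop = FALSE]
}

# single-linkage cluster ids under >= recip reciprocal overlap, same copy_state
overlap_clusters <- function(cnvs, recip) {
  n <- nrow(cnvs)
  if (n == 0) return(integer(0))
  edges <- integer(0)
  for (key in unique(paste(cnvs$chrom, cnvs$copy_state))) {
    idx <- which(paste(cnvs$chrom, cnvs$copy_state) == key)
    if (length(idx) < 2) next
    ir <- as_iranges0(cnvs$start[idx], cnvs$end[idx])
    hits <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
    ok <- ov >= recip * IRanges::width(ir[qi]) & ov >= recip * IRanges::width(ir[si])
    if (any(ok)) edges <- c(edges, rbind(idx[qi[ok]], idx[si[ok]]))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::components(g)$membership
}

#' Remove CNVs overlapping known risk loci
#'
#' Used for the sensitivity re-analysis that asks whether enrichment signal
#' survives once established loci are excluded. A call is removed when it
#' overlaps any locus interval by at least one base.
#'
#' @param cnvs CNV tibble.
#' @param loci Region tibble of known loci.
#' @return Filtered CNV tibble (row order preserved).
#' @export
remove_known_loci <- function(cnvs, loci) {
  validate_cnvs(cnvs)
  loci <- normalize_regions(loci)
  cnvs[!overlaps_any(cnvs, loci), , drop = FALSE]
}

#' Run the full CNV quality-control chain
#'
#' Applies, in order: fragment joining, the low-copy-repeat overlap filter,
#' the probe-density filter, the frequency filter, and the size/probe-count
#' filter. An optional externally derived list of samples passing intensity
#' QC can be supplied; calls from other samples are dropped first.
#'
#' @param cnvs CNV tibble.
#' @param lcr Region tibble of low-copy repeats, or `NULL` to skip.
#' @param probes Probe map tibble, or `NULL` to use stored probe counts.
#' @param n_samples Total genotyped samples, for the frequency filter.
#' @param pass_samples Optional character vector of sample ids passing
#'   upstream sample-level QC.
#' @param min_len,min_probes,max_freq,recip_overlap,min_density,max_lcr_frac
#'   QC thresholds; see the individual filters.
#' @return Analysis-ready CNV tibble.
#' @export
cnv_qc <- function(cnvs, lcr = NULL, probes = NULL, n_samples,
                   pass_samples = NULL, min_len = 1e5, min_probes = 15,
                   max_freq = 0.01, recip_overlap = 0.5,
                   min_density = 1 / 20000, max_lcr_frac = 0.5) {
  validate_cnvs(cnvs)
  if (!is.null(pass_samples)) {
    cnvs <- filter(cnvs, .data$sample_id %in% pass_samples)
  }
  cnvs <- merge_adjacent(cnvs)
  if (!is.null(lcr)) cnvs <- filter_lcr(cnvs, lcr, max_lcr_frac)
  cnvs <- filter_probe_density(cnvs, probes, min_density)
  cnvs <- filter_frequency(cnvs, n_samples, max_freq, recip_overlap)
  filter_size_probes(cnvs, min_len, min_probes)
}
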