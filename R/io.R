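#' Read a CNV call table
#'
#' Reads a tab-separated table of post-calling CNVs with columns `sample_id`,
#' `chrom`, `start`, `end`, `copy_state` (`DEL`/`DUP`, case-insensitive),
#' `n_probes`, `study`, `chip` and `phenotype` (1 = case, 0 = control).
#' Coordinates are stored internally as 0-based half-open intervals; BED-style
#' input is taken as-is and 1-based inclusive input is converted on read.
#'
#' @param path Path to the TSV file.
#' @param coords Coordinate dialect of the input: `"bed"` (0-based half-open,
#'   the default) or `"1based"` (1-based inclusive, converted on read).
#' @return A tibble of CNV calls, one row per call.
#' @export
read_cnv_table <- function(path, coords = c("bed", "1based")) {
  coords <- match.arg(coords)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(cnv_required_cols, names(x))
  if (length(missing) > 0) {
    abort(paste0("CNV file ", path, " is missing columns: ",
      paste(missing, collapse = ", ")))
  }
  x <- mutate(x,
    sample_id = as.character(.data$sample_id),
    chrom = as.character(.data$chrom),
    start = as.numeric(.data$start),
    end = as.numeric(.data$end),
    copy_state = tolower(as.character(.data$copy_state)),
    n_probes = as.integer(.data$n_probes),
    study = as.character(.data$study),
    chip = as.character(.data$chip),
    phenotype = as.integer(.data$phenotype)
  )
  if (coords == "1based") {
    x <- mutate(x, start = .data$start - 1)
  }
  validate_cnvs(x)
  x
}

#' Read a BED region file
#'
#' Reads a 3+ column BED file (chrom, start, end, optional name) into a
#' normalized region tibble (0-based half-open, sorted within chromosome).
#' Used for low-copy-repeat masks and known-locus lists.
#'
#' @param path Path to the BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present in
#'   the file, `name`.
#' @export
read_regions_bed <- function(path) {
  # fill = TRUE tolerates files mixing 3- and 4-column lines
  x <- as_tibble(utils::read.table(path, sep = "\t", header = FALSE,
    fill = TRUE, quote = "", stringsAsFactors = FALSE))
  if (ncol(x) < 3) abort(paste0("BED file ", path, " has fewer than 3 columns"))
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4) names(x)[4] <- "name"
  x <- select(x, all_of(intersect(c("chrom", "start", "end", "name"), names(x))))
  x <- mutate(x, chrom = as.character(.data$chrom),
    start = as.numeric(.data$start), end = as.numeric(.data$end))
  normalize_regions(x)
}

#' Read a probe position map
#'
#' Reads a 2-column TSV (`chrom`, `pos`; 0-based positions) describing the
#' genotyping array probes, used by the probe-density filter.
#'
#' @param path Path to the TSV file (no header).
#' @return A tibble with columns `chrom` and `pos`, sorted within chromosome.
#' @export
read_probe_map <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "pos"), show_col_types = FALSE)
  x <- mutate(x, chrom = as.character(.data$chrom), pos = as.numeric(.data$pos))
  x <- dplyr::arrange(x, .data$chrom, .data$pos)
  dup <- x |> group_by(.data$chrom) |>
    summarise(bad = anyDuplicated(.data$pos) > 0) |> dplyr::pull(.data$bad)
  if (any(dup)) abort("probe map has duplicated positions within a chromosome")
  x
}

#' Read a gene coordinate table
#'
#' Accepts BED4 (chrom, start, end, gene_id; no header) or a headered TSV with
#' columns `gene_id`, `chrom`, `start`, `end`. Gene spans are full transcript
#' spans; a gene is "hit" when a CNV overlaps any part of this span.
#'
#' @param path Path to the gene file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("gene_id", first)) {
    x <- readr::read_tsv(path, show_col_types = FALSE)
    missing <- setdiff(c("gene_id", "chrom", "start", "end"), names(x))
    if (length(missing) > 0) {
      abort(paste0("gene file missing columns: ", paste(missing, collapse = ", ")))
    }
  } else {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
      show_col_types = FALSE)
  }
  x <- mutate(x, gene_id = as.character(.data$gene_id),
    chrom = as.character(.data$chrom),
    start = as.numeric(.data$start), end = as.numeric(.data$end))
  if (anyDuplicated(x$gene_id)) abort("gene_id values must be unique")
  if (any(x$end <= x$start)) abort("gene table contains spans with end <= start")
  select(x, "gene_id", "chrom", "start", "end")
}

#' Read gene sets in GMT format
#'
#' Each line holds a set name, a description, and tab-separated member gene
#' identifiers. Duplicate members within a line are dropped.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nms <- map_chr(parts, 1)
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate gene set names in ", path, ": ",
      paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  sets <- map(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 3) {
      abort(paste0("GMT line ", i, " (", p[1], ") has no member genes"))
    }
    unique(p[-(1:2)])
  })
  setNames(sets, nms)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  validate_sets(sets)
  lines <- map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write an annotated CNV table
#'
#' Writes the tibble as TSV with the `genes_hit` list-column flattened to a
#' comma-joined string.
#'
#' @param cnvs Annotated CNV tibble (see [annotate_cnvs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_table <- function(cnvs, path) {
  out <- cnvs
  if ("genes_hit" %in% names(out)) {
    out$genes_hit <- map_chr(out$genes_hit, paste, collapse = ",")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
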