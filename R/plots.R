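# ggplot2 displays for result tables.

#' Forest plot of gene-set enrichment results
#'
#' Odds ratios with 95% confidence intervals per set, ordered by one-sided
#' p value; sets passing the adjusted threshold are highlighted.
#'
#' @param object A `cnv_enrichment` tibble.
#' @param alpha_adj Highlighting threshold on `p_adj` (default 0.05).
#' @param max_sets Show at most this many sets, smallest p first (default
#'   30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_enrichment
#' @export
autoplot.cnv_enrichment <- function(object, alpha_adj = 0.05, max_sets = 30,
                                    ...) {
  d <- arrange(as_tibble(object), .data$p_one_sided)
  d <- head(d, max_sets)
  d$set_name <- factor(d$set_name, levels = rev(d$set_name))
  d$associated <- d$p_adj < alpha_adj
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$set_name,
    colour = .data$associated)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
      xmax = .data$ci_hi), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
      `TRUE` = "firebrick"), name = paste0("p_adj < ", alpha_adj)) +
    ggplot2::labs(x = "odds ratio per set gene hit (log scale)", y = NULL,
      title = unique(object$analysis)) +
    ggplot2::theme_minimal()
}

#' Observed versus expected enriched-set counts
#'
#' Bar display of the permutation excess test: observed counts of sets below
#' each p-value threshold against the mean permuted count.
#'
#' @param object A `cnv_excess` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnv_excess
#' @export
autoplot.cnv_excess <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
    c("n_obs", "n_exp"), names_to = "quantity", values_to = "count")
  d$quantity <- c(n_obs = "observed", n_exp = "expected")[d$quantity]
  d$p_thr <- paste0("p < ", d$p_thr)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$p_thr, y = .data$count,
    fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "significance threshold", y = "gene sets",
      fill = NULL) +
    ggplot2::theme_minimal()
}

#' Diagnostic display of CNV size distributions
#'
#' Density of CNV length (log10 kb) by copy-state and phenotype, a quick
#' check of a dataset or a simulation against expectations.
#'
#' @param cnvs Annotated CNV tibble.
#' @return A ggplot object.
#' @export
plot_cnv_sizes <- function(cnvs) {
  validate_cnvs(cnvs, annotated = TRUE)
  d <- mutate(as_tibble(cnvs),
    phenotype = ifelse(.data$phenotype == 1, "case", "control"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size_kb,
    colour = .data$phenotype)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~copy_state) +
    ggplot2::labs(x = "CNV size (kb, log scale)", y = "density",
      colour = NULL) +
    ggplot2::theme_minimal()
}
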