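# ggplot2 views of the main result types.

.volcano_palette <- c(red = "#c0392b", blue = "#2e6da4", grey = "grey55",
                      black = "black", undefined = "orange")

#' Volcano plot of a group comparison
#'
#' Fold change (log2) against -log10 p, colored by the four-way
#' classification: red = significant and beyond the fold-change cutoff,
#' blue = significant only, grey = large fold change only, black = neither.
#' Dot size tracks the absolute percentage-point difference, so abundant
#' features with modest fold changes stay visible.
#'
#' @param results Output of [compare_groups()].
#' @param fc_cutoff,p_cutoff Guide-line positions (defaults 1.5, 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, fc_cutoff = 1.5, p_cutoff = 0.05) {
  d <- filter(results, !is.na(.data$fc), .data$fc > 0)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = log2(.data$fc), y = -log10(.data$p),
                 colour = .data$class, size = abs(.data$pp))
  ) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_cutoff), log2(fc_cutoff)),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff),
                        linetype = "dashed", colour = "grey70") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = .volcano_palette) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  size = "|pp|", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of footprint enrichment results
#'
#' Odds ratio against -log10 p per node; the strongest, most significant
#' footprints sit in the upper right. Marked nodes (e.g. a phenotype class
#' under test) are highlighted.
#'
#' @param footprints Output of [footprint_enrichment()].
#' @param marked Optional character vector of node ids to highlight.
#' @return A ggplot object.
#' @export
plot_footprint <- function(footprints, marked = NULL) {
  d <- mutate(footprints,
              marked = if (is.null(marked)) FALSE else
                .data$node %in% marked)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$odds_ratio, y = -log10(.data$p),
                    colour = .data$marked)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#c0392b"),
                                 guide = if (is.null(marked)) "none" else
                                   "legend") +
    ggplot2::labs(x = "odds ratio", y = "-log10 p", colour = "marked") +
    ggplot2::theme_minimal()
}

#' Modification load by group
#'
#' Mean acetyl or methyl groups per histone molecule per group, with
#' per-replicate points.
#'
#' @param load_tbl Output of [modification_load()] with a grouping column.
#' @param group_col Column to group by (default `"temperature"`).
#' @return A ggplot object.
#' @export
plot_modification_load <- function(load_tbl, group_col = "temperature") {
  ggplot2::ggplot(
    load_tbl,
    ggplot2::aes(x = .data[[group_col]], y = .data$load)
  ) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(y = "groups per molecule") +
    ggplot2::theme_minimal()
}
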