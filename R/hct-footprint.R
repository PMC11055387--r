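# Consensome construction, high-confidence transcriptional target (HCT)
# designation, and gene-set footprint enrichment.

#' Build a consensome from per-dataset peak strengths
#'
#' Genes are scored by their mean peak strength across datasets (a gene
#' missing from a dataset contributes 0 by default, or the dataset mean with
#' `missing = "mean"`), ranked in descending score order with average-rank
#' ties, and assigned percentiles 100 * (1 - (rank - 1) / m). Ties share a
#' rank and hence a percentile. Percentiles are invariant under monotone
#' transformations of the scores.
#'
#' @param strengths Tibble with `gene`, `dataset`, `peak_strength` for one
#'   node (a `node` column, if present, must be constant).
#' @param missing `"zero"` (default) or `"mean"`: imputation for genes
#'   absent from a dataset.
#' @return A `consensome`: tibble `gene`, `score`, `rank`, `percentile`,
#'   sorted by rank, with the node id as an attribute.
#' @export
build_consensome <- function(strengths, missing = c("zero", "mean")) {
  missing <- match.arg(missing)
  stopifnot(all(c("gene", "dataset", "peak_strength") %in% names(strengths)))
  if (nrow(strengths) == 0) abort("empty peak-strength matrix")
  node <- if ("node" %in% names(strengths)) {
    u <- unique(strengths$node)
    if (length(u) > 1) abort("build_consensome() expects a single node")
    u
  } else NA_character_
  datasets <- unique(strengths$dataset)
  wide <- strengths |>
    distinct(.data$gene, .data$dataset, .keep_all = TRUE) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "dataset",
                       values_from = "peak_strength")
  mat <- as.matrix(wide[, datasets, drop = FALSE])
  if (missing == "zero") {
    mat[is.na(mat)] <- 0
  } else {
    for (j in seq_len(ncol(mat))) {
      mat[is.na(mat[, j]), j] <- mean(mat[, j], na.rm = TRUE)
    }
  }
  score <- rowMeans(mat)
  m <- length(score)
  rk <- rank(-score, ties.method = "average")
  out <- tibble(
    gene = wide$gene,
    score = score,
    rank = rk,
    percentile = 100 * (1 - (rk - 1) / m)
  ) |> arrange(.data$rank)
  attr(out, "node") <- node
  class(out) <- c("consensome", class(out))
  out
}

#' High-confidence transcriptional targets of a consensome
#'
#' Genes in the 95th percentile (the top 5 percent) of the node's
#' consensome. Under the reporting convention that the top-ranked gene sits
#' at percentile 100, membership is strictly above the cutoff line: for m
#' distinct scores this selects exactly the top 5 percent (a gene exactly on
#' the 95 line is the (0.05 m + 1)-th and is out). With every score tied the
#' ranking is uninformative; that degenerate case returns all genes with a
#' warning.
#'
#' @param consensome Output of [build_consensome()].
#' @param percentile HCT cutoff (default 95).
#' @return Character vector of gene ids.
#' @export
hct_set <- function(consensome, percentile = 95) {
  stopifnot(all(c("gene", "percentile", "score") %in% names(consensome)))
  if (nrow(consensome) < 20) {
    abort("consensome too small (< 20 genes) for HCT designation")
  }
  if (length(unique(consensome$score)) == 1) {
    warn("degenerate consensome: all scores tied, every gene is an HCT")
    return(consensome$gene)
  }
  consensome$gene[consensome$percentile > percentile]
}

#' Footprint enrichment of a gene set against node HCT sets
#'
#' For each node, the overlap between the query gene set and the node's HCT
#' set is tested with the hypergeometric upper tail over the gene universe;
#' p-values are Benjamini-Hochberg adjusted across nodes, and results are
#' sorted by q then descending odds ratio. A node with a larger intersection
#' than chance (q < 0.05) has evidence of a regulatory footprint within the
#' gene set.
#'
#' @param gene_set Character vector of genes (must lie in `universe`).
#' @param hct_sets Named list of HCT gene vectors, one per node.
#' @param universe Gene universe; defaults to the union of all HCT sets and
#'   the gene set (configurable because enrichment backgrounds matter).
#' @param direction Optional tag recorded in the result (e.g. `"induced"`).
#' @return Tibble `node`, `intersection`, `odds_ratio`, `p`, `q`,
#'   `direction`.
#' @export
footprint_enrichment <- function(gene_set, hct_sets, universe = NULL,
                                 direction = NA_character_) {
  stopifnot(is.list(hct_sets), length(hct_sets) >= 1,
            !is.null(names(hct_sets)))
  universe <- universe %||% unique(c(unlist(hct_sets), gene_set))
  if (length(universe) == 0) abort("empty gene universe")
  if (!all(gene_set %in% universe)) {
    abort("gene_set must be a subset of the universe")
  }
  gene_set <- unique(gene_set)
  res <- purrr::map_dfr(names(hct_sets), function(nd) {
    hct <- unique(intersect(hct_sets[[nd]], universe))
    k <- length(intersect(gene_set, hct))
    hg <- hypergeom_enrichment(k, K = length(hct), n = length(gene_set),
                               N = length(universe))
    tibble(node = nd, intersection = k, odds_ratio = hg$odds_ratio,
           p = hg$p)
  })
  res$q <- bh_adjust(res$p)
  res$direction <- direction
  res |> arrange(.data$q, dplyr::desc(.data$odds_ratio))
}

#' Enrichment of a marked node class among top-ranked footprint nodes
#'
#' Tests whether nodes of a marked class (for example, nodes annotated to
#' thermoregulatory phenotypes) are over-represented among the `top_k`
#' best-ranked footprint nodes, with the hypergeometric upper tail: N =
#' universe of nodes analyzed, K = marked nodes, n = top_k, k = overlap.
#' `top_k` has no natural default and must be chosen explicitly. Ranking by
#' q (then odds ratio) and by odds ratio are both available.
#'
#' @param footprints Result of [footprint_enrichment()].
#' @param marked Character vector of marked node ids (subset of the
#'   universe).
#' @param top_k How many top-ranked nodes to consider.
#' @param universe_size Number of nodes in the universe; defaults to
#'   `nrow(footprints)`.
#' @param rank_by `"q"` (default: q then odds ratio) or `"odds_ratio"`.
#' @return One-row tibble `overlap`, `top_k`, `K`, `N`, `p`.
#' @export
node_class_enrichment <- function(footprints, marked, top_k,
                                  universe_size = nrow(footprints),
                                  rank_by = c("q", "odds_ratio")) {
  rank_by <- match.arg(rank_by)
  if (top_k > universe_size) abort("top_k exceeds the node universe")
  if (!all(marked %in% footprints$node)) {
    abort("marked nodes must appear in the footprint results")
  }
  ranked <- if (rank_by == "q") {
    arrange(footprints, .data$q, dplyr::desc(.data$odds_ratio))
  } else {
    arrange(footprints, dplyr::desc(.data$odds_ratio))
  }
  top <- head(ranked$node, top_k)
  k <- length(intersect(top, marked))
  hg <- hypergeom_enrichment(k, K = length(unique(marked)), n = top_k,
                             N = universe_size)
  tibble(overlap = k, top_k = top_k, K = length(unique(marked)),
         N = universe_size, p = hg$p)
}
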