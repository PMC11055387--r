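# Quantitation semantics on proteoform percent-abundance tables.
#
# A table is a long tibble with one row per (proteoform, replicate):
# required columns `proteoform` (canonical label), `replicate`, `abundance`
# (percent of the histone family, summing to 100 per replicate); any other
# columns (tissue, temperature, sample ids) are carried as metadata.

.meta_cols <- function(table) {
  setdiff(names(table), c("proteoform", "abundance"))
}

.check_table <- function(table) {
  need <- c("proteoform", "replicate", "abundance")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(paste0("abundance table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(table$abundance < -1e-9)) abort("abundances must be non-negative")
  invisible(table)
}

#' Validate a proteoform abundance table
#'
#' Checks the schema and that every replicate sums to 100 within `tol`.
#'
#' @param table Long abundance tibble (see package docs).
#' @param tol Allowed deviation of per-replicate sums from 100.
#' @return The table, invisibly; errors otherwise.
#' @export
validate_abundance_table <- function(table, tol = 0.1) {
  .check_table(table)
  sums <- table |>
    group_by(across(all_of(.meta_cols(table)))) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  bad <- abs(sums$total - 100) > tol
  if (any(bad)) {
    abort(paste0(sum(bad), " replicate(s) do not sum to 100 (tolerance ",
                 tol, ")"))
  }
  invisible(table)
}

# Parse each distinct label once; returns a tibble (label, site, kind) with
# no rows for <un>.
.label_ptm_map <- function(labels, backbone) {
  labels <- unique(labels)
  purrr::map_dfr(labels, function(lb) {
    p <- parse_notation(lb, backbone)
    pt <- p$ptms
    if (backbone$n_term_ac_fixed) pt <- pt[pt$site != 0L, ]
    if (nrow(pt) == 0) return(tibble(label = character(), site = integer(),
                                     kind = character()))
    tibble(label = lb, site = pt$site, kind = pt$kind)
  })
}

# Which labels satisfy a ptm_query?
.labels_matching_query <- function(labels, query) {
  vapply(unique(labels), function(lb) {
    satisfies_query(parse_notation(lb, query$backbone), query)
  }, TRUE)
}

.per_replicate <- function(table, weights, value_name = "abundance") {
  # weights: named numeric per proteoform label (e.g. 0/1 membership or
  # modification counts); returns per-replicate weighted sums.
  table |>
    mutate(.w = weights[.data$proteoform]) |>
    group_by(across(all_of(.meta_cols(table)))) |>
    summarise("{value_name}" := sum(.data$abundance * .data$.w),
              .groups = "drop")
}

#' Abundance of one exact proteoform per replicate
#'
#' Angle-bracket semantics: the abundance of the single proteoform carrying
#' exactly the listed marks; 0 if it is absent from the table.
#'
#' @param table Abundance table.
#' @param spec An angle-bracket label, e.g. `"<K9me2K27me1>"`.
#' @param backbone The matching [histone_backbone()].
#' @return Tibble of replicate metadata plus `abundance`.
#' @export
abundance_exact <- function(table, spec, backbone) {
  .check_table(table)
  p <- parse_notation(spec, backbone)
  if (!inherits(p, "proteoform")) {
    abort("abundance_exact() expects an exact <...> label")
  }
  canon <- format_notation(p)
  labs <- unique(table$proteoform)
  w <- setNames(as.numeric(vapply(labs, function(lb) {
    format_notation(parse_notation(lb, backbone)) == canon
  }, TRUE)), labs)
  .per_replicate(table, w)
}

#' Summed abundance of all proteoforms containing the queried marks
#'
#' Curly-bracket semantics: every proteoform satisfying all constraints
#' contributes. `"un"` site constraints match absence; disjunctions
#' (`"me2/3"`) match either degree.
#'
#' @inheritParams abundance_exact
#' @param spec A curly-bracket query, e.g. `"{K9me2/3}"`.
#' @return Tibble of replicate metadata plus `abundance`.
#' @export
abundance_containing <- function(table, spec, backbone) {
  .check_table(table)
  q <- parse_notation(spec, backbone)
  if (inherits(q, "proteoform")) {
    abort("abundance_containing() expects a {...} query")
  }
  labs <- unique(table$proteoform)
  w <- setNames(as.numeric(.labels_matching_query(labs, q)), labs)
  .per_replicate(table, w)
}

#' Percent of histone with at least one acetylation
#'
#' Sums proteoforms carrying one or more side-chain acetyl groups. The fixed
#' (H4) or any explicit N-terminal acetylation is excluded unless
#' `include_n_terminal = TRUE`.
#'
#' @inheritParams abundance_exact
#' @param include_n_terminal Count the N-terminal acetylation as well?
#' @return Tibble of replicate metadata plus `abundance`.
#' @export
any_acetyl <- function(table, backbone, include_n_terminal = FALSE) {
  .check_table(table)
  labs <- unique(table$proteoform)
  w <- setNames(vapply(labs, function(lb) {
    p <- parse_notation(lb, backbone)
    cnt <- modification_counts(p)
    n <- if (include_n_terminal) cnt$n_acetyl_total else cnt$n_acetyl_side_chain
    as.numeric(n >= 1)
  }, 0), labs)
  .per_replicate(table, w)
}

#' Average number of acetyl or methyl groups per histone molecule
#'
#' The abundance of each proteoform is multiplied by its number of acetyl
#' groups (or methyl groups, where me1/me2/me3 contribute 1/2/3), summed,
#' and divided by 100 -- giving groups per molecule because abundances are
#' percent of total histone.
#'
#' @inheritParams any_acetyl
#' @param kind `"acetyl"` or `"methyl"`.
#' @param include_n_terminal For `kind = "acetyl"`, include the N-terminal
#'   acetylation in the count (default `FALSE`: side-chain groups only, so
#'   the H4 fixed N-terminal acetyl does not add a constant 1).
#' @return Tibble of replicate metadata plus `load`.
#' @export
modification_load <- function(table, backbone, kind = c("acetyl", "methyl"),
                              include_n_terminal = FALSE) {
  .check_table(table)
  kind <- match.arg(kind)
  labs <- unique(table$proteoform)
  w <- setNames(vapply(labs, function(lb) {
    cnt <- modification_counts(parse_notation(lb, backbone))
    if (kind == "acetyl") {
      if (include_n_terminal) cnt$n_acetyl_total else cnt$n_acetyl_side_chain
    } else {
      cnt$n_methyl_groups
    }
  }, 0L), labs)
  out <- .per_replicate(table, w / 100, value_name = "load")
  out
}

#' Percentage-point difference
#'
#' The signed difference of two percent abundances, a - b. Because
#' abundances are percent of total histone, this difference reads directly
#' as the share of the genome whose nucleosomes changed state.
#'
#' @param a,b Percent abundances.
#' @return Signed difference in percentage points.
#' @examples
#' pp_difference(6.0, 1.7)
#' @export
pp_difference <- function(a, b) a - b

#' Fold change of two percent abundances
#'
#' a / b. A zero denominator is flagged as undefined (NA with a warning),
#' never returned as infinity, so downstream classification can report the
#' record instead of silently dropping it.
#'
#' @param a,b Percent abundances (numerator, denominator).
#' @return Ratio, or NA where `b` is 0.
#' @examples
#' fold_change(36, 39.4)
#' @export
fold_change <- function(a, b) {
  out <- ifelse(b > 0, a / b, NA_real_)
  if (any(b == 0)) {
    warn("fold change undefined where the denominator abundance is 0")
  }
  out
}

#' Abundance of every k-PTM containment combination
#'
#' Enumerates all k-subsets of the site/kind marks observed anywhere in the
#' table and evaluates each as a containment query; combinations with zero
#' total abundance are omitted.
#'
#' @inheritParams abundance_exact
#' @param k Combination order (1 = discrete PTM marginals, 2 = binary, 3 =
#'   ternary).
#' @return Tibble with `combination` plus replicate metadata and `abundance`.
#' @export
enumerate_combinations <- function(table, k, backbone) {
  .check_table(table)
  stopifnot(k >= 1)
  pm <- .label_ptm_map(table$proteoform, backbone)
  marks <- distinct(pm, .data$site, .data$kind) |> arrange(.data$site, .data$kind)
  if (nrow(marks) < k) {
    abort("k exceeds the number of marks observed in the table")
  }
  idx <- combn(nrow(marks), k)
  keep_one_site <- apply(idx, 2, function(j) !anyDuplicated(marks$site[j]))
  idx <- idx[, keep_one_site, drop = FALSE]
  labs <- unique(table$proteoform)
  out <- purrr::map_dfr(seq_len(ncol(idx)), function(jcol) {
    j <- idx[, jcol]
    q <- ptm_query(backbone, tibble(site = marks$site[j],
                                    kinds = as.list(marks$kind[j])))
    w <- setNames(as.numeric(.labels_matching_query(labs, q)), labs)
    res <- .per_replicate(table, w)
    res$combination <- format_notation(q)
    res
  })
  totals <- out |>
    group_by(.data$combination) |>
    summarise(total = sum(.data$abundance), .groups = "drop")
  out |>
    inner_join(filter(totals, .data$total > 0), by = "combination") |>
    select("combination", dplyr::everything(), -"total")
}

#' Compare groups on proteoform-level features
#'
#' Computes per-replicate feature values at the requested level, averages
#' technical replicates within a biological sample when `sample_col` is
#' given, then tests group differences: Welch's two-tailed t for two groups,
#' one-way ANOVA with Tukey HSD for three or more. Every contrast reports
#' both the percentage-point difference and the fold change, and is
#' classified by the conventional volcano rules (p < `p_cutoff` and fold
#' change beyond `fc_cutoff` or its reciprocal): `red` = significant and
#' large-fold, `blue` = significant only, `grey` = large-fold only, `black`
#' = neither. Undefined fold changes (zero denominator mean) leave `fc` NA
#' and mark the record.
#'
#' @param table Abundance table; must contain the grouping column.
#' @param group_col Name of the grouping column (e.g. `"tissue"`).
#' @param backbone The matching [histone_backbone()].
#' @param level `"exact"` (each proteoform), `"containment"` (single-mark
#'   marginals), `"combination"` (k-PTM combinations, see `k`), or `"load"`
#'   (acetyl and methyl groups per molecule).
#' @param k Combination order when `level = "combination"`.
#' @param sample_col Optional column identifying biological samples whose
#'   technical replicates are averaged before testing.
#' @param p_cutoff,fc_cutoff Classification thresholds (defaults 0.05 and
#'   1.5).
#' @return Tidy tibble: `feature`, `level`, `contrast`, `mean_a`, `mean_b`,
#'   `pp`, `fc`, `p`, `p_overall` (ANOVA only), `class`.
#' @export
compare_groups <- function(table, group_col, backbone,
                           level = c("exact", "containment", "combination",
                                     "load"),
                           k = 2, sample_col = NULL,
                           p_cutoff = 0.05, fc_cutoff = 1.5) {
  .check_table(table)
  level <- match.arg(level)
  if (!group_col %in% names(table)) {
    abort(paste0("grouping column '", group_col, "' not found"))
  }

  feats <- switch(
    level,
    exact = {
      tmp <- table |>
        tidyr::complete(
          .data$proteoform,
          tidyr::nesting(!!!rlang::syms(.meta_cols(table))),
          fill = list(abundance = 0)
        )
      tmp |> rename(feature = "proteoform", value = "abundance")
    },
    containment = {
      pm <- .label_ptm_map(table$proteoform, backbone)
      marks <- distinct(pm, .data$site, .data$kind)
      purrr::map_dfr(seq_len(nrow(marks)), function(i) {
        q <- ptm_query(backbone, tibble(site = marks$site[i],
                                        kinds = list(marks$kind[i])))
        labs <- unique(table$proteoform)
        w <- setNames(as.numeric(.labels_matching_query(labs, q)), labs)
        .per_replicate(table, w) |>
          mutate(feature = format_notation(q))
      }) |> rename(value = "abundance")
    },
    combination = {
      enumerate_combinations(table, k, backbone) |>
        rename(feature = "combination", value = "abundance")
    },
    load = {
      bind_rows(
        modification_load(table, backbone, "acetyl") |>
          mutate(feature = "acetyl_load") |> rename(value = "load"),
        modification_load(table, backbone, "methyl") |>
          mutate(feature = "methyl_load") |> rename(value = "load")
      )
    }
  )

  if (!is.null(sample_col)) {
    feats <- feats |>
      group_by(.data$feature, across(all_of(c(group_col, sample_col)))) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }

  groups <- sort(unique(as.character(feats[[group_col]])))
  if (length(groups) < 2) abort("need at least two groups")
  counts <- feats |>
    distinct(across(all_of(group_col)),
             across(any_of(c(sample_col, "replicate")))) |>
    dplyr::count(across(all_of(group_col)))
  if (any(counts$n < 2)) abort("every group needs >= 2 replicates")

  out <- feats |>
    group_by(.data$feature) |>
    dplyr::group_modify(function(df, key) {
      vals <- split(df$value, as.character(df[[group_col]]))
      vals <- vals[groups]
      if (length(groups) == 2) {
        ht <- welch_t(vals[[2]], vals[[1]])
        contrasts <- tibble(
          contrast = paste(groups[2], "-", groups[1]),
          mean_a = mean(vals[[1]]), mean_b = mean(vals[[2]]),
          p = ht$p, p_overall = NA_real_
        )
      } else {
        ht <- anova_tukey(vals)
        pairs <- combn(groups, 2)
        contrasts <- tibble(
          contrast = paste(pairs[2, ], "-", pairs[1, ]),
          mean_a = unname(vapply(pairs[1, ], function(g) mean(vals[[g]]), 0)),
          mean_b = unname(vapply(pairs[2, ], function(g) mean(vals[[g]]), 0)),
          p = ht$pairwise$p_adj[match(paste(pairs[2, ], "-", pairs[1, ]),
                                      ht$pairwise$contrast)],
          p_overall = ht$p
        )
      }
      contrasts
    }) |>
    ungroup()

  out |>
    mutate(
      level = level,
      pp = pp_difference(.data$mean_b, .data$mean_a),
      fc = ifelse(.data$mean_a > 0, .data$mean_b / .data$mean_a, NA_real_),
      fc_defined = .data$mean_a > 0,
      class = dplyr::case_when(
        is.na(.data$fc) ~ "undefined",
        .data$p < p_cutoff &
          (.data$fc > fc_cutoff | .data$fc < 1 / fc_cutoff) ~ "red",
        .data$p < p_cutoff ~ "blue",
        .data$fc > fc_cutoff | .data$fc < 1 / fc_cutoff ~ "grey",
        TRUE ~ "black"
      )
    ) |>
    select("feature", "level", "contrast", "mean_a", "mean_b", "pp", "fc",
           "fc_defined", "p", "p_overall", "class")
}

#' Round results the way comparative reports print them
#'
#' Abundances and pp to 1 decimal place, fold changes to 2; full precision
#' is retained in the input, this only formats a reporting copy.
#'
#' @param results Output of [compare_groups()].
#' @return The tibble with rounded `mean_a`, `mean_b`, `pp`, `fc`.
#' @export
round_for_report <- function(results) {
  results |>
    mutate(
      mean_a = round(.data$mean_a, 1),
      mean_b = round(.data$mean_b, 1),
      pp = round(.data$pp, 1),
      fc = round(.data$fc, 2)
    )
}
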