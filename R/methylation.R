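# Region-level differential methylation from bisulfite CpG calls, and the
# inverse-association integration with differential expression.
#
# Coordinates: CpG calls carry 1-based positions (the Bismark coverage
# dialect); regions are half-open 0-based internally (BED dialect), so a CpG
# at 1-based position p falls in region [start, end) iff start < p <= end in
# 1-based terms, i.e. start <= p - 1 < end.

#' Read a Bismark-format coverage file
#'
#' Columns: chromosome, start, end (1-based, start == end for a CpG),
#' percent methylation, methylated count, unmethylated count.
#'
#' @param path File path.
#' @param sample Sample id attached to every row.
#' @param group Group label attached to every row.
#' @return Tibble `sample`, `group`, `chrom`, `pos`, `strand`, `meth`,
#'   `unmeth`.
#' @export
read_bismark_coverage <- function(path, sample = basename(path),
                                  group = NA_character_) {
  cols <- readr::cols(
    chrom = readr::col_character(), start = readr::col_integer(),
    end = readr::col_integer(), pct = readr::col_double(),
    meth = readr::col_integer(), unmeth = readr::col_integer()
  )
  d <- readr::read_tsv(path, col_names = names(cols$cols), col_types = cols,
                       progress = FALSE)
  if (any(is.na(d$meth) | is.na(d$unmeth))) {
    bad <- which(is.na(d$meth) | is.na(d$unmeth))[1]
    abort(paste0("malformed coverage line ", bad, " in ", path))
  }
  tibble(sample = sample, group = group, chrom = d$chrom, pos = d$start,
         strand = "+", meth = d$meth, unmeth = d$unmeth)
}

#' Filter CpG calls on minimum read coverage
#'
#' Retains bases with coverage (methylated + unmethylated) of at least
#' `min_cov` reads; the default of 10 is the conventional reliability
#' threshold for bisulfite calls. Idempotent.
#'
#' @param calls CpG call tibble (`meth`, `unmeth` columns).
#' @param min_cov Minimum coverage.
#' @return Filtered tibble.
#' @export
filter_coverage <- function(calls, min_cov = 10) {
  filter(calls, .data$meth + .data$unmeth >= min_cov)
}

#' Normalize coverage between samples by median scaling
#'
#' Each sample's counts are scaled by factor_s = median(per-sample median
#' coverages) / median_s and rounded half-up, equalizing the median coverage
#' distributions while preserving each base's methylation percentage within
#' rounding.
#'
#' @param calls CpG call tibble with a `sample` column (>= 2 samples).
#' @return The tibble with scaled `meth`/`unmeth` counts and a
#'   `scale_factor` attribute (named per sample).
#' @export
normalize_coverage <- function(calls) {
  samples <- unique(calls$sample)
  if (length(samples) < 2) abort("normalization needs >= 2 samples")
  med <- calls |>
    mutate(cov = .data$meth + .data$unmeth) |>
    group_by(.data$sample) |>
    summarise(med = median(.data$cov), .groups = "drop")
  if (any(med$med == 0)) abort("a sample has zero coverage everywhere")
  target <- median(med$med)
  factors <- setNames(target / med$med, med$sample)
  round_half_up <- function(x) floor(x + 0.5)
  out <- calls |>
    mutate(
      .f = factors[.data$sample],
      meth = as.integer(round_half_up(.data$meth * .data$.f)),
      unmeth = as.integer(round_half_up(.data$unmeth * .data$.f))
    ) |>
    select(-".f")
  attr(out, "scale_factor") <- factors
  out
}

#' Summarize CpG calls over promoter and gene-body regions
#'
#' Promoters are TSS +/- `promoter_window` bp, strand-aware (the TSS of a
#' minus-strand gene is its annotation end); gene bodies are the full
#' annotated span. Counts are summed over member CpGs per sample; regions
#' with no covered CpG are omitted (and listed in the `dropped` attribute).
#' Intervals are half-open 0-based internally; annotation `start`/`end` are
#' taken 0-based half-open as in BED (`coords = "bed"`), or 1-based
#' inclusive with `coords = "onebased"`.
#'
#' @param calls CpG call tibble (`sample`, `group`, `chrom`, `pos`, counts).
#' @param annotation Tibble `gene`, `chrom`, `start`, `end`, `strand`.
#' @param promoter_window Half-width of the promoter window in bp (default
#'   1000).
#' @param kinds Region kinds to produce (`"promoter"`, `"gene_body"`).
#' @param coords Coordinate dialect of `annotation`.
#' @return Region-by-sample count tibble: `region`, `gene`, `kind`,
#'   `chrom`, `start`, `end`, `strand`, `sample`, `group`, `meth`,
#'   `unmeth`.
#' @export
summarize_regions <- function(calls, annotation, promoter_window = 1000,
                              kinds = c("promoter", "gene_body"),
                              coords = c("bed", "onebased")) {
  coords <- match.arg(coords)
  kinds <- match.arg(kinds, several.ok = TRUE)
  ann <- as_tibble(annotation)
  if (coords == "onebased") {
    ann$start <- ann$start - 1L
  }
  tss <- ifelse(ann$strand == "-", ann$end, ann$start)
  regions <- bind_rows(
    if ("promoter" %in% kinds) {
      tibble(gene = ann$gene, kind = "promoter", chrom = ann$chrom,
             start = pmax(tss - promoter_window, 0L),
             end = tss + promoter_window, strand = ann$strand)
    },
    if ("gene_body" %in% kinds) {
      tibble(gene = ann$gene, kind = "gene_body", chrom = ann$chrom,
             start = ann$start, end = ann$end, strand = ann$strand)
    }
  )
  regions$region <- paste0(regions$gene, ":", regions$kind)

  # interval assignment per chromosome via findInterval on sorted region
  # starts with bounded backtracking (regions may overlap, e.g. a promoter
  # inside a neighboring gene body)
  calls0 <- mutate(select(calls, -any_of("strand")), pos0 = .data$pos - 1L)
  hits <- purrr::map_dfr(unique(regions$chrom), function(ch) {
    reg <- regions[regions$chrom == ch, ]
    reg <- reg[order(reg$start), ]
    cl <- calls0[calls0$chrom == ch, ]
    if (nrow(reg) == 0 || nrow(cl) == 0) return(tibble())
    maxlen <- max(reg$end - reg$start)
    hi <- findInterval(cl$pos0, reg$start)
    pairs_call <- integer(0); pairs_reg <- integer(0)
    k <- 0L
    repeat {
      idx <- hi - k
      live <- idx >= 1L
      if (!any(live)) break
      ok <- live & reg$start[pmax(idx, 1L)] > cl$pos0 - maxlen
      if (!any(ok)) break
      inside <- ok & cl$pos0 < reg$end[pmax(idx, 1L)]
      pairs_call <- c(pairs_call, which(inside))
      pairs_reg <- c(pairs_reg, idx[inside])
      k <- k + 1L
    }
    bind_cols(cl[pairs_call, ],
              select(reg[pairs_reg, ], -"chrom"))
  })

  out <- hits |>
    group_by(.data$region, .data$gene, .data$kind, .data$chrom,
             .data$start, .data$end, .data$strand, .data$sample,
             .data$group) |>
    summarise(meth = sum(.data$meth), unmeth = sum(.data$unmeth),
              .groups = "drop")
  dropped <- setdiff(regions$region, out$region)
  if (length(dropped)) {
    rlang::inform(paste0(length(dropped),
                         " region(s) had no covered CpG and were omitted"))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Differential methylation of regions between two groups
#'
#' Per region, fits a binomial logistic regression of (methylated,
#' unmethylated) counts on group and tests the group term with a likelihood
#' ratio test; with fewer than two samples in either group it falls back to
#' Fisher's exact test on pooled counts. The methylation difference is the
#' difference of group mean percent methylation (`group_a` minus
#' `group_b`, so name the changed condition first to give hypomethylation a
#' negative sign). q-values are Benjamini-Hochberg; regions are called
#' `hyper`/`hypo` when q < `q_cutoff` and |difference| > `diff_cutoff`
#' percentage points, else `ns`.
#'
#' @param region_counts Output of [summarize_regions()].
#' @param group_a,group_b Group labels to contrast (difference = A - B).
#' @param q_cutoff,diff_cutoff Call thresholds (defaults 0.05 and 5).
#' @return Tibble `region`, `gene`, `kind`, `meth_diff`, `p`, `q`, `call`.
#' @export
differential_regions <- function(region_counts, group_a, group_b,
                                 q_cutoff = 0.05, diff_cutoff = 5) {
  d <- filter(region_counts, .data$group %in% c(group_a, group_b))
  if (nrow(d) == 0) abort("no rows for the requested groups")
  res <- d |>
    group_by(.data$region, .data$gene, .data$kind) |>
    dplyr::group_modify(function(df, key) {
      a <- df[df$group == group_a, ]
      b <- df[df$group == group_b, ]
      cov_a <- a$meth + a$unmeth
      cov_b <- b$meth + b$unmeth
      if (sum(cov_a) == 0 || sum(cov_b) == 0) {
        return(tibble(meth_diff = NA_real_, p = NA_real_))
      }
      pct_a <- mean(100 * a$meth / cov_a)
      pct_b <- mean(100 * b$meth / cov_b)
      if (nrow(a) < 2 || nrow(b) < 2) {
        tab <- matrix(c(sum(a$meth), sum(a$unmeth),
                        sum(b$meth), sum(b$unmeth)), nrow = 2)
        p <- stats::fisher.test(tab)$p.value
      } else {
        grp <- factor(c(rep("a", nrow(a)), rep("b", nrow(b))),
                      levels = c("b", "a"))
        y <- rbind(cbind(a$meth, a$unmeth), cbind(b$meth, b$unmeth))
        fit1 <- stats::glm(y ~ grp, family = stats::binomial())
        fit0 <- stats::glm(y ~ 1, family = stats::binomial())
        p <- stats::pchisq(fit0$deviance - fit1$deviance,
                           df = 1, lower.tail = FALSE)
      }
      tibble(meth_diff = pct_a - pct_b, p = p)
    }) |>
    ungroup() |>
    filter(!is.na(.data$p))
  res$q <- bh_adjust(res$p)
  res$call <- ifelse(
    res$q < q_cutoff & abs(res$meth_diff) > diff_cutoff,
    ifelse(res$meth_diff > 0, "hyper", "hypo"),
    "ns"
  )
  res
}

#' Flag genes whose promoter methylation is inversely associated with
#' expression
#'
#' Joins differential methylation calls with a differential expression
#' table and flags genes where promoter hypomethylation coincides with
#' up-regulation, or hypermethylation with down-regulation -- the canonical
#' inverse relationship of promoter methylation and transcription. DM
#' thresholds: q < `dm_q` and |meth_diff| > `dm_diff`; DEG thresholds:
#' p_adj < `deg_p` and |log2FC| >= `deg_lfc` (default 0.263 = log2 of a 20
#' percent change). Same-direction pairs are excluded.
#'
#' @param dm Differential methylation tibble ([differential_regions()]
#'   output); promoter rows are used if a `kind` column is present.
#' @param deg DEG tibble: `gene`, `log2FC`, `p_adj`.
#' @param dm_q,dm_diff,deg_p,deg_lfc Thresholds.
#' @return Tibble `gene`, `meth_diff`, `meth_q`, `fold_change`, `log2FC`,
#'   `expr_p_adj`, `association` (`"hypo-up"` / `"hyper-down"`), sorted by
#'   methylation difference.
#' @export
integrate_expression <- function(dm, deg, dm_q = 0.05, dm_diff = 5,
                                 deg_p = 0.05, deg_lfc = 0.263) {
  if ("kind" %in% names(dm)) dm <- filter(dm, .data$kind == "promoter")
  if (anyDuplicated(dm$gene)) {
    rlang::inform("duplicate gene ids in DM records; keeping first match")
    dm <- dm[!duplicated(dm$gene), ]
  }
  if (anyDuplicated(deg$gene)) {
    rlang::inform("duplicate gene ids in DEG records; keeping first match")
    deg <- deg[!duplicated(deg$gene), ]
  }
  joined <- inner_join(
    select(dm, "gene", "meth_diff", meth_q = "q"),
    select(deg, "gene", "log2FC", expr_p_adj = "p_adj"),
    by = "gene"
  )
  joined |>
    filter(
      .data$meth_q < dm_q, abs(.data$meth_diff) > dm_diff,
      .data$expr_p_adj < deg_p, abs(.data$log2FC) >= deg_lfc,
      sign(.data$meth_diff) != sign(.data$log2FC)
    ) |>
    mutate(
      fold_change = 2^.data$log2FC,
      association = ifelse(.data$meth_diff < 0, "hypo-up", "hyper-down")
    ) |>
    select("gene", "meth_diff", "meth_q", "fold_change", "log2FC",
           "expr_p_adj", "association") |>
    arrange(.data$meth_diff)
}
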