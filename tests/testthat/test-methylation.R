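# RRBS coverage handling, region summaries, differential methylation,
# expression integration.

toy_calls <- function() {
  tibble::tibble(
    sample = "s1", group = "g",
    chrom = "chr1", pos = c(100L, 150L, 200L), strand = "+",
    meth = c(5L, 9L, 10L), unmeth = c(5L, 0L, 0L)
  )
}

test_that("coverage filtering keeps the documented boundary and is
           idempotent", {
  calls <- toy_calls()
  kept <- filter_coverage(calls, min_cov = 10)
  expect_equal(kept$pos, c(100L, 200L))   # coverage 9 dropped, 10 kept
  expect_identical(filter_coverage(kept, 10), kept)
  empty <- filter_coverage(calls[0, ], 10)
  expect_equal(nrow(empty), 0)
})

test_that("median scaling normalizes coverage and preserves percentages", {
  calls <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 3),
    group = "g", chrom = "chr1", pos = rep(c(1L, 2L, 3L), 3), strand = "+",
    meth = c(10L, 10L, 10L, 5L, 5L, 5L, 10L, 10L, 10L),
    unmeth = c(30L, 30L, 30L, 15L, 15L, 15L, 10L, 10L, 10L)
  )
  # medians: a = 40, b = 20, c = 20 -> cohort median 20
  out <- normalize_coverage(calls)
  f <- attr(out, "scale_factor")
  expect_equal(unname(f[c("a", "b", "c")]), c(0.5, 1, 1))
  a <- out[out$sample == "a", ]
  expect_equal(a$meth, rep(5L, 3))
  expect_equal(a$unmeth, rep(15L, 3))
  # per-base methylation percentage invariant under scaling
  expect_equal(a$meth / (a$meth + a$unmeth), rep(0.25, 3))
  same <- normalize_coverage(calls[calls$sample != "a", ])
  expect_equal(unname(attr(same, "scale_factor")), c(1, 1))
  expect_error(normalize_coverage(calls[calls$sample == "a", ]),
               ">= 2 samples")
})

test_that("region summaries follow the half-open, strand-aware convention", {
  ann <- tibble::tibble(
    gene = c("plus", "minus"), chrom = "chr1",
    start = c(1000L, 9000L), end = c(3000L, 11000L),
    strand = c("+", "-")
  )
  calls <- tibble::tibble(
    sample = "s1", group = "g", chrom = "chr1",
    # 1-based positions: 500 inside the plus promoter [0,2000); 2000 is the
    # 0-based coordinate 1999, still inside; 2001 (0-based 2000) excluded
    pos = c(500L, 2000L, 2001L, 1500L, 11500L, 12001L),
    strand = "+",
    meth = c(5L, 10L, 3L, 15L, 4L, 2L), unmeth = c(5L, 0L, 1L, 5L, 4L, 2L)
  )
  out <- suppressMessages(summarize_regions(calls, ann))
  prom_plus <- out[out$region == "plus:promoter", ]
  # promoter of the plus gene: TSS 1000 -> [0, 2000): positions 500, 1500
  # and 2000 (0-based 1999) are in; 2001 (0-based 2000) is out (half-open)
  expect_equal(prom_plus$meth, 5L + 15L + 10L)
  expect_equal(prom_plus$unmeth, 5L + 5L + 0L)
  expect_equal(100 * prom_plus$meth / (prom_plus$meth + prom_plus$unmeth),
               75)
  # minus-strand gene: TSS = end = 11000 -> promoter [10000, 12000) extends
  # downstream in genome coordinates; 11500 in, 12001 (0-based 12000) out
  prom_minus <- out[out$region == "minus:promoter", ]
  expect_equal(prom_minus$meth, 4L)
  # gene body [1000, 3000): 1500, 2000 and 2001 are members
  body_plus <- out[out$region == "plus:gene_body", ]
  expect_equal(body_plus$meth, 15L + 10L + 3L)
})

test_that("differential methylation calls planted regions and only them", {
  # identical groups: no calls
  base <- tibble::tibble(
    region = "r1:promoter", gene = "r1", kind = "promoter",
    chrom = "chr1", start = 0L, end = 2000L, strand = "+",
    sample = c("a1", "a2", "b1", "b2"),
    group = c("A", "A", "B", "B"),
    meth = c(50L, 52L, 51L, 50L), unmeth = c(50L, 48L, 49L, 50L)
  )
  res <- differential_regions(base, "A", "B")
  expect_equal(res$call, "ns")
  expect_equal(res$meth_diff, 0.5, tolerance = 1.5)

  # planted 90 vs 10 percent, coverage 100 per sample, n = 4 per group
  strong <- tibble::tibble(
    region = "hot:promoter", gene = "hot", kind = "promoter",
    chrom = "chr1", start = 0L, end = 2000L, strand = "+",
    sample = c(paste0("a", 1:4), paste0("b", 1:4)),
    group = rep(c("A", "B"), each = 4),
    meth = c(rbinom(4, 100, 0.9), rbinom(4, 100, 0.1)),
    unmeth = 0L
  )
  set.seed(77)
  strong$meth <- c(rbinom(4, 100, 0.9), rbinom(4, 100, 0.1))
  strong$unmeth <- 100L - strong$meth
  res2 <- differential_regions(strong, "A", "B")
  expect_equal(res2$meth_diff, 80, tolerance = 8)
  expect_lt(res2$q, 1e-6)
  expect_equal(res2$call, "hyper")
  # agreeing with a Fisher-exact oracle on the pooled counts
  pooled <- matrix(c(sum(strong$meth[1:4]), sum(strong$unmeth[1:4]),
                     sum(strong$meth[5:8]), sum(strong$unmeth[5:8])), 2)
  expect_lt(fisher.test(pooled)$p.value, 1e-6)

  # fewer than two samples per group falls back to Fisher pooling
  single <- strong[c(1, 5), ]
  res3 <- differential_regions(single, "A", "B")
  expect_lt(res3$p, 1e-6)
})

test_that("region counts conserve the underlying base counts", {
  mc <- gen_methylome_cohort(seed = 41, n_regions = 30, n_planted = 3)
  reg <- suppressMessages(
    summarize_regions(mc$calls, mc$annotation, kinds = "promoter")
  )
  per_sample_region <- tapply(reg$meth, reg$sample, sum)
  per_sample_base <- tapply(mc$calls$meth, mc$calls$sample, sum)
  for (s in names(per_sample_region)) {
    expect_lte(per_sample_region[[s]], per_sample_base[[s]])
  }
})

test_that("inverse-association integration flags the canonical patterns", {
  # rows built from the published integration-table values
  dm <- tibble::tibble(
    gene = c("Car13", "Tpcn2", "SameDir", "WeakDiff"),
    kind = "promoter",
    meth_diff = c(-30.66, 14.30, -20, -2),
    p = 0, q = c(4.79e-38, 8.34e-5, 1e-10, 1e-10),
    call = c("hypo", "hyper", "hypo", "ns")
  )
  deg <- tibble::tibble(
    gene = c("Car13", "Tpcn2", "SameDir", "WeakDiff"),
    log2FC = c(log2(1.53), log2(0.54), -1, 1),
    p_adj = c(1.24e-7, 2.90e-3, 1e-5, 1e-5)
  )
  out <- integrate_expression(dm, deg)
  expect_setequal(out$gene, c("Car13", "Tpcn2"))
  expect_equal(out$association[out$gene == "Car13"], "hypo-up")
  expect_equal(out$fold_change[out$gene == "Car13"], 1.53,
               tolerance = 1e-9)
  expect_equal(out$association[out$gene == "Tpcn2"], "hyper-down")
  expect_equal(out$fold_change[out$gene == "Tpcn2"], 0.54,
               tolerance = 1e-9)
  # output is a subset of DM-called x DEG genes
  expect_true(all(out$gene %in% intersect(dm$gene, deg$gene)))
})

test_that("planted methylome cohorts recover through the full chain", {
  mc <- gen_methylome_cohort(seed = 19)
  calls <- normalize_coverage(filter_coverage(mc$calls))
  reg <- suppressMessages(
    summarize_regions(calls, mc$annotation, kinds = "promoter")
  )
  dm <- differential_regions(reg, "SC", "TN")
  flagged <- integrate_expression(dm, mc$deg)
  planted <- mc$truth$gene[mc$truth$direction != "none"]
  expect_gte(mean(planted %in% flagged$gene), 0.9)
  hypo <- mc$truth$gene[mc$truth$direction == "hypo"]
  expect_true(all(flagged$association[flagged$gene %in% hypo] == "hypo-up"))
})
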