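# Generators: determinism, invariants, planted-truth recovery.

test_that("generators are pure functions of their seed", {
  a <- gen_proteoform_cohort("H4", seed = 5,
                             design = tibble::tibble(tissue = "BAT",
                                                     temperature = "TN",
                                                     n = 2L))
  b <- gen_proteoform_cohort("H4", seed = 5,
                             design = tibble::tibble(tissue = "BAT",
                                                     temperature = "TN",
                                                     n = 2L))
  expect_identical(a, b)
  c <- gen_proteoform_cohort("H4", seed = 6,
                             design = tibble::tibble(tissue = "BAT",
                                                     temperature = "TN",
                                                     n = 2L))
  expect_false(identical(a$table$abundance, c$table$abundance))
  w1 <- gen_consensome_world(seed = 4, n_nodes = 5, universe_size = 300,
                             geneset_size = 30)
  w2 <- gen_consensome_world(seed = 4, n_nodes = 5, universe_size = 300,
                             geneset_size = 30)
  expect_identical(w1, w2)
  # the caller's RNG stream is untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_methylome_cohort(seed = 2, n_regions = 5,
                                              n_planted = 0))
  expect_identical(runif(1), before)
})

test_that("generated abundance tables satisfy the simplex invariant", {
  co <- gen_proteoform_cohort("H3.2", seed = 8)
  expect_silent(validate_abundance_table(
    dplyr::select(co$table, "proteoform", "replicate", "abundance"),
    tol = 1e-6
  ))
  expect_true(all(co$table$abundance >= 0))
  # null world: group means agree within sampling error
  null <- gen_proteoform_cohort(
    "H4", seed = 9, profile = "random", n_proteoforms = 10, sigma = 0.05,
    design = tibble::tibble(tissue = "BAT", temperature = c("TN", "SC"),
                            n = c(5L, 5L))
  )
  m <- tapply(null$table$abundance,
              list(null$table$proteoform, null$table$temperature), mean)
  expect_lt(max(abs(m[, 1] - m[, 2])), 3)
})

test_that("study profiles encode the cohort characteristics exactly", {
  h3 <- bb_h3(); h4 <- bb_h4()
  for (fam in c("H3.2", "H4")) {
    for (tis in c("BAT", "liver")) {
      for (tmp in c("TN", "RT", "SC")) {
        pr <- study_profile(fam, tis, tmp)
        expect_equal(sum(pr$abundance), 100, tolerance = 1e-9)
        expect_true(all(pr$abundance >= 0))
      }
    }
  }
  sc <- study_profile("H3.2", "BAT", "SC"); sc$replicate <- "r"
  expect_equal(any_acetyl(sc, h3)$abundance, 45.2, tolerance = 1e-9)
  expect_equal(modification_load(sc, h3, "acetyl")$load, 0.63,
               tolerance = 1e-9)
  tn <- study_profile("H3.2", "BAT", "TN"); tn$replicate <- "r"
  expect_equal(any_acetyl(tn, h3)$abundance, 35.6, tolerance = 1e-9)
  h4sc <- study_profile("H4", "BAT", "SC"); h4sc$replicate <- "r"
  expect_equal(any_acetyl(h4sc, h4)$abundance, 39.4, tolerance = 1e-9)
  expect_equal(modification_load(h4sc, h4, "acetyl")$load, 0.46,
               tolerance = 1e-9)
  # the tissue-distinctive proteoforms at room temperature
  bat <- study_profile("H3.2", "BAT", "RT"); bat$replicate <- "r"
  liv <- study_profile("H3.2", "liver", "RT"); liv$replicate <- "r"
  expect_equal(abundance_exact(bat, "<K9me2K27me1>", h3)$abundance, 6.0)
  expect_equal(abundance_exact(liv, "<K9me2K27me1>", h3)$abundance, 1.7)
})

test_that("planted containment effects are recovered end to end", {
  h4 <- bb_h4()
  co <- gen_proteoform_cohort(
    "H4", seed = 23, profile = "random", n_proteoforms = 12, sigma = 0.05,
    design = tibble::tibble(tissue = "BAT", temperature = c("TN", "SC"),
                            n = c(5L, 5L)),
    effects = list(list(group = "SC", mark = "{K16ac}", delta_pp = 5))
  )
  truth_gap <-
    sum(co$truth$abundance[co$truth$temperature == "SC" &
                             grepl("K16ac", co$truth$proteoform)]) -
    sum(co$truth$abundance[co$truth$temperature == "TN" &
                             grepl("K16ac", co$truth$proteoform)])
  expect_equal(truth_gap, 5, tolerance = 1e-9)
  res <- compare_groups(co$table, "temperature", h4, level = "containment")
  hit <- res[res$feature == "{K16ac}", ]
  expect_lt(hit$p, 0.05)
  # an effect too large for the simplex errors
  expect_error(
    gen_proteoform_cohort(
      "H4", seed = 23, profile = "random", n_proteoforms = 6,
      design = tibble::tibble(tissue = "BAT", temperature = c("TN", "SC"),
                              n = c(2L, 2L)),
      effects = list(list(group = "SC", mark = "{K16ac}", delta_pp = 500))
    ),
    "below 0|matches all or none"
  )
})

test_that("fragment ppm jitter interacts with the tolerance as expected", {
  h4 <- bb_h4()
  truth <- tibble::tibble(proteoform = c("<K16acK20me2>", "<K20me3>"),
                          abundance = c(50, 50))
  match_rate <- function(frag_ppm, seed) {
    run <- gen_topdown_run(truth, h4, seed = seed, frag_ppm = frag_ppm)
    theo <- unique(unlist(lapply(truth$proteoform, function(lb) {
      generate_cz_ions(parse_notation(lb, h4))$neutral_mass
    })))
    obs <- unlist(lapply(run$ms2, function(s) {
      neutral_mass(s$fragments$mz, s$fragments$z)
    }))
    mean(vapply(obs, function(m) {
      any(abs(m - theo) / theo * 1e6 <= 10)
    }, TRUE))
  }
  expect_equal(match_rate(2.5, 51), 1)     # modest jitter: all within 10 ppm
  expect_lt(match_rate(15, 52), 0.5)       # heavy jitter: most lost
})

test_that("methylome files round-trip losslessly", {
  dir <- tempfile("meth")
  mc <- gen_methylome_cohort(seed = 33, n_regions = 10, n_planted = 2,
                             dir = dir)
  f <- mc$files$coverage[[1]]
  expect_true(file.exists(f))
  back <- read_bismark_coverage(f, sample = "TN_1", group = "TN")
  orig <- mc$calls[mc$calls$sample == "TN_1", ]
  expect_equal(back$pos, orig$pos)
  expect_equal(back$meth, orig$meth)
  expect_equal(back$unmeth, orig$unmeth)
  ann <- read_bed_annotation(mc$files$annotation)
  expect_equal(ann$gene, mc$annotation$gene)
  expect_equal(ann$start, mc$annotation$start)
  deg <- readr::read_csv(mc$files$deg, show_col_types = FALSE)
  expect_equal(deg$log2FC, mc$deg$log2FC)
})

test_that("consensome worlds couple planted regulators to the gene set", {
  w <- gen_consensome_world(seed = 61, n_nodes = 10, n_planted = 2,
                            universe_size = 1000, geneset_size = 100,
                            overlap_rate = 0.5)
  for (nd in w$planted) {
    d <- w$strengths[w$strengths$node == nd, ]
    hct <- hct_set(build_consensome(d))
    expect_equal(length(intersect(hct, w$gene_set)) / length(hct), 0.5,
                 tolerance = 0.1)
  }
  null_node <- setdiff(unique(w$strengths$node), w$planted)[1]
  d0 <- w$strengths[w$strengths$node == null_node, ]
  chance <- length(intersect(hct_set(build_consensome(d0)), w$gene_set)) /
    (1000 * 0.05)
  expect_lt(chance, 0.3)
})
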