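# Quantitation semantics on abundance tables.

test_that("exact-proteoform abundance reads a single molecular state", {
  tab <- toy_h4_table()
  h4 <- bb_h4()
  expect_equal(abundance_exact(tab, "<K20me2>", h4)$abundance, 40)
  expect_equal(abundance_exact(tab, "<K20me1>", h4)$abundance, 0)
  expect_error(abundance_exact(tab, "{K20me2}", h4), "exact")
})

test_that("containment queries sum every carrier", {
  h4 <- bb_h4(); h3 <- bb_h3()
  tab <- toy_h4_table()
  expect_equal(abundance_containing(tab, "{K20me2}", h4)$abundance, 65)
  t2 <- tibble::tibble(
    proteoform = c("<K9me2>", "<K14ac>", "<un>"),
    abundance = c(30, 30, 40), replicate = "r1"
  )
  expect_equal(abundance_containing(t2, "{K9un}", h3)$abundance, 70)
  t3 <- tibble::tibble(
    proteoform = c("<K9me2>", "<K9me3>", "<K9me1>"),
    abundance = c(10, 5, 85), replicate = "r1"
  )
  expect_equal(abundance_containing(t3, "{K9me2/3}", h3)$abundance, 15)
  # containment dominates exact for every shared spec
  expect_gte(abundance_containing(tab, "{K20me2}", h4)$abundance,
             abundance_exact(tab, "<K20me2>", h4)$abundance)
})

test_that("any_acetyl counts side-chain acetylation and complements to 100", {
  h4 <- bb_h4()
  tab <- toy_h4_table()
  expect_equal(any_acetyl(tab, h4)$abundance, 25)
  none <- tibble::tibble(proteoform = c("<K20me2>", "<un>"),
                         abundance = c(70, 30), replicate = "r1")
  expect_equal(any_acetyl(none, h4)$abundance, 0)
  # fixed N-terminal ac is not a side-chain acetylation, but counts when
  # asked for
  expect_equal(any_acetyl(none, h4, include_n_terminal = TRUE)$abundance,
               100)
  zero_ac <- 100 - any_acetyl(tab, h4)$abundance
  expect_equal(any_acetyl(tab, h4)$abundance + zero_ac, 100,
               tolerance = 1e-6)
})

test_that("modification load is abundance-weighted groups per molecule", {
  h4 <- bb_h4()
  tab <- toy_h4_table()
  expect_equal(modification_load(tab, h4, "methyl")$load,
               (40 * 2 + 25 * 2 + 20 * 3) / 100)
  expect_equal(modification_load(tab, h4, "acetyl")$load, 0.25)
  un <- tibble::tibble(proteoform = "<un>", abundance = 100,
                       replicate = "r1")
  expect_equal(modification_load(un, h4, "methyl")$load, 0)
  # linearity in the table: load of a 30/70 blend is the blend of loads
  t1 <- toy_h4_table(); t2 <- un
  blend <- tibble::tibble(
    proteoform = c(t1$proteoform, t2$proteoform),
    abundance = c(t1$abundance * 0.3, t2$abundance * 0.7),
    replicate = "r1"
  )
  expect_equal(
    modification_load(blend, h4, "methyl")$load,
    0.3 * modification_load(t1, h4, "methyl")$load +
      0.7 * modification_load(t2, h4, "methyl")$load,
    tolerance = 1e-9
  )
})

test_that("pp difference and fold change report the printed worked pairs", {
  expect_equal(pp_difference(6.0, 1.7), 4.3)
  expect_equal(pp_difference(3.7, 1.6), 2.1)
  expect_equal(pp_difference(5, 5), 0)
  expect_equal(round(fold_change(36, 39.4), 2), 0.91)
  expect_equal(fold_change(70, 50), 1.4)
  expect_lt(fold_change(70, 50), 1.5)   # large pp, small fold
  expect_equal(pp_difference(70, 50), 20)
  expect_equal(fold_change(7, 7), 1)
  expect_warning(fc0 <- fold_change(5, 0), "undefined")
  expect_true(is.na(fc0))
})

test_that("k-PTM combination enumeration matches containment sums", {
  h4 <- bb_h4()
  tab <- toy_h4_table()
  k2 <- enumerate_combinations(tab, 2, h4)
  expect_equal(nrow(k2), 1)
  expect_equal(k2$combination, "{K16acK20me2}")
  expect_equal(k2$abundance, 25)
  k1 <- enumerate_combinations(tab, 1, h4)
  for (i in seq_len(nrow(k1))) {
    expect_equal(
      k1$abundance[i],
      abundance_containing(tab, k1$combination[i], h4)$abundance
    )
  }
})

test_that("group comparison classifies by p and fold change", {
  h4 <- bb_h4()
  set.seed(11)
  # identical groups: p in the 1 region, class black
  base <- toy_h4_table()
  tab <- purrr::map_dfr(1:3, function(r) {
    dplyr::bind_rows(
      dplyr::mutate(base, replicate = paste0("a", r), grp = "A"),
      dplyr::mutate(base, replicate = paste0("b", r), grp = "B")
    )
  })
  res <- suppressWarnings(compare_groups(tab, "grp", h4, level = "exact"))
  expect_true(all(res$p == 1))
  expect_true(all(res$class == "black"))
  expect_equal(res$fc, rep(1, nrow(res)))

  # planted +10 pp shift on a containment mark is detected
  co <- gen_proteoform_cohort(
    "H4", seed = 31, profile = "random", n_proteoforms = 10, sigma = 0.05,
    design = tibble::tibble(tissue = "BAT", temperature = c("TN", "SC"),
                            n = c(4L, 4L)),
    effects = list(list(group = "SC", mark = "{K20me2}", delta_pp = 10))
  )
  res2 <- compare_groups(co$table, "temperature", h4, level = "containment")
  hit <- res2[res2$feature == "{K20me2}", ]
  expect_lt(hit$p, 0.05)
  expect_equal(abs(hit$pp), 10, tolerance = 3)
  expect_true(hit$class %in% c("red", "blue"))
})

test_that("three-group comparisons use ANOVA with Tukey-adjusted contrasts", {
  h4 <- bb_h4()
  co <- gen_proteoform_cohort(
    "H4", seed = 13, profile = "random", n_proteoforms = 8, sigma = 0.05,
    design = tibble::tibble(tissue = "BAT",
                            temperature = c("TN", "RT", "SC"),
                            n = c(4L, 4L, 4L))
  )
  res <- compare_groups(co$table, "temperature", h4, level = "load")
  expect_setequal(unique(res$feature), c("acetyl_load", "methyl_load"))
  expect_equal(nrow(res), 2 * 3)         # three pairwise contrasts each
  expect_true(all(!is.na(res$p_overall)))
  # pp and fc stay mutually consistent with the group means
  expect_equal(res$pp, res$mean_b - res$mean_a, tolerance = 1e-9)
  expect_equal(res$fc[res$fc_defined],
               (res$mean_b / res$mean_a)[res$fc_defined], tolerance = 1e-9)
})

test_that("technical replicates are averaged before testing", {
  h4 <- bb_h4()
  co <- gen_proteoform_cohort(
    "H4", seed = 17, profile = "random", n_proteoforms = 6, sigma = 0.10,
    design = tibble::tibble(tissue = "BAT", temperature = c("TN", "SC"),
                            n = c(3L, 3L)),
    n_tech_reps = 2L
  )
  res <- compare_groups(co$table, "temperature", h4, level = "exact",
                        sample_col = "sample")
  # averaging two technical replicates halves the replicate count per group
  manual <- co$table |>
    dplyr::group_by(.data$proteoform, .data$temperature, .data$sample) |>
    dplyr::summarise(value = mean(.data$abundance), .groups = "drop")
  one <- manual[manual$proteoform == manual$proteoform[1], ]
  ht <- welch_t(one$value[one$temperature == "TN"],
                one$value[one$temperature == "SC"])
  expect_equal(res$p[res$feature == manual$proteoform[1]], ht$p,
               tolerance = 1e-12)
})

test_that("abundance tables validate their simplex invariant", {
  tab <- toy_h4_table()
  expect_silent(validate_abundance_table(tab))
  bad <- tab; bad$abundance[1] <- 60
  expect_error(validate_abundance_table(bad), "sum to 100")
  neg <- tab; neg$abundance[1] <- -1
  expect_error(validate_abundance_table(neg), "non-negative")
})
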