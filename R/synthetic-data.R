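# Seeded generators giving every pipeline stage planted-truth inputs with
# the statistical structure the analysis assumes. All generators are pure
# functions of their arguments and a seed: the same call reproduces the same
# output bitwise, and the caller's RNG state is left untouched.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# A single global seed fans out to per-stage child seeds so partial runs
# reproduce without replaying earlier stages.
.child_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 7919) %% 2147483629
}

#' Study-condition proteoform truth profiles
#'
#' Returns the designed "true" proteoform composition of one histone family
#' in one tissue/housing-temperature condition of the emulated cold-stress
#' cohort (brown adipose tissue and liver from mice housed thermoneutral,
#' room temperature, or severe cold). The profiles are constructed so their
#' containment marginals carry the cohort's group-level characteristics:
#' bulk acetylation percentages (H3.2 rising from 35.6 to 45.2 percent from
#' TN to SC in BAT; H4 from 36.9 to 39.4), side-chain acetyl loads (H3.2 BAT
#' 0.51 to 0.63 acetylations per molecule), the dominant H4 K20 methylation
#' states (<K20me2> 36 in BAT vs 39.4 in liver at RT, <K20me3> 22 vs 19,
#' <K20me1> 4.7 vs 5.4), and the tissue-distinctive H3.2 proteoforms
#' (<K9me2K27me1> 6.0 in BAT vs 1.7 in liver; <K9me3K27me1> 3.3 vs 0.5;
#' <K9me2K27me3K36me1> 1.6 vs 3.7). These are synthetic compositions, not
#' measured data: they give the quantitation algebra a ground truth with
#' realistic structure.
#'
#' @param family `"H3.2"` or `"H4"`.
#' @param tissue `"BAT"` or `"liver"`.
#' @param temperature `"TN"`, `"RT"`, or `"SC"`.
#' @return Tibble `proteoform`, `abundance` summing to exactly 100.
#' @export
study_profile <- function(family = c("H3.2", "H4"),
                          tissue = c("BAT", "liver"),
                          temperature = c("TN", "RT", "SC")) {
  family <- match.arg(family)
  tissue <- match.arg(tissue)
  temperature <- match.arg(temperature)
  key <- paste(tissue, temperature)

  if (family == "H4") {
    acet <- c("BAT TN" = 36.9, "BAT RT" = 36.8, "BAT SC" = 39.4,
              "liver TN" = 36.0, "liver RT" = 36.2, "liver SC" = 37.0)[[key]]
    load <- c("BAT TN" = 0.42, "BAT RT" = 0.42, "BAT SC" = 0.46,
              "liver TN" = 0.42, "liver RT" = 0.43, "liver SC" = 0.45)[[key]]
    # unacetylated mass splits in fixed tissue proportions derived from the
    # RT composition (K20me1 / K20me2 / K20me3 / unmodified)
    props <- if (tissue == "BAT") c(4.7, 36.0, 22.0, 0.5) / 63.2 else
      c(5.4, 39.4, 19.0, 0.0) / 63.8
    unacet <- (100 - acet) * props
    di <- 100 * load - acet          # di-acetyl share fixes the load
    mono_plain <- 2.5                # acetylated but K20-unmethylated
    mono_me <- acet - di - mono_plain
    stopifnot(di > 0, mono_me > 0)
    tab <- tibble(
      proteoform = c("<K20me1>", "<K20me2>", "<K20me3>", "<un>",
                     "<K16ac>", "<K16acK20me2>", "<K8acK16acK20me3>"),
      abundance = c(unacet, mono_plain, mono_me, di)
    )
  } else {
    acet <- c("BAT TN" = 35.6, "BAT RT" = 43.1, "BAT SC" = 45.2,
              "liver TN" = 38.0, "liver RT" = 40.0, "liver SC" = 40.0)[[key]]
    load <- c("BAT TN" = 0.51, "BAT RT" = 0.61, "BAT SC" = 0.63,
              "liver TN" = 0.60, "liver RT" = 0.65, "liver SC" = 0.62)[[key]]
    planted <- if (tissue == "BAT") {
      c("<K9me2K27me1>" = 6.0, "<K9me3K27me1>" = 3.3,
        "<K9me2K27me3K36me1>" = 1.6)
    } else {
      c("<K9me2K27me1>" = 1.7, "<K9me3K27me1>" = 0.5,
        "<K9me2K27me3K36me1>" = 3.7)
    }
    di <- 100 * load - acet
    mono <- acet - di
    stopifnot(di > 0, mono > 0)
    ac_forms <- c("<K9me2K23acK36me1>" = 0.4 * mono,
                  "<K14acK27me2>" = 0.6 * mono,
                  "<K14acK23acK27me2>" = di)
    # methylation-only filler; the K9me2 weight grows with cold so the
    # {K9me2} marginal rises and {K9un} falls at severe cold
    w_k9me2 <- if (tissue == "BAT") {
      c(TN = 2.0, RT = 2.5, SC = 3.5)[[temperature]]
    } else 2.0
    filler_w <- c("<K9me2>" = w_k9me2, "<K9me3>" = 1.5,
                  "<K9me2K27me2>" = 1.5, "<K9me2K36me1>" = 1.0,
                  "<K27me2>" = 2.0, "<K4me1K27me2>" = 1.5,
                  "<K9me1K27me2>" = 1.0, "<K27me3>" = 1.0,
                  "<K9me1K36me2>" = 0.8, "<un>" = 0.2)
    rest <- 100 - acet - sum(planted)
    stopifnot(rest > 0)
    filler <- filler_w / sum(filler_w) * rest
    tab <- tibble(
      proteoform = c(names(planted), names(ac_forms), names(filler)),
      abundance = unname(c(planted, ac_forms, filler))
    )
  }
  stopifnot(abs(sum(tab$abundance) - 100) < 1e-9, all(tab$abundance >= 0))
  tab
}

#' Default cohort design of the emulated study
#'
#' 3-5 animals per housing temperature and tissue.
#'
#' @return Tibble `tissue`, `temperature`, `n`.
#' @export
study_design <- function() {
  tibble(
    tissue = rep(c("BAT", "liver"), each = 3),
    temperature = rep(c("TN", "RT", "SC"), 2),
    n = c(4L, 5L, 5L, 4L, 4L, 4L)
  )
}

# Logistic-normal jitter: multiplicative log-normal noise on the simplex,
# renormalized to 100, so abundances stay non-negative and sum exactly.
.jitter_abundances <- function(abund, sigma) {
  a <- abund * exp(rnorm(length(abund), 0, sigma))
  a / sum(a) * 100
}

#' Generate a proteoform abundance cohort with planted truth
#'
#' Draws per-replicate abundance tables around per-group truth compositions.
#' By default the truth compositions are the [study_profile()]s over the
#' [study_design()]; alternatively a random world can be generated
#' (`profile = "random"`) with `n_proteoforms` proteoforms and optional
#' planted group effects.
#'
#' An effect spec is a list with `group` (a value of the grouping column),
#' `mark` (a containment query string) and `delta_pp`: the containment
#' marginal of `mark` in that group is shifted by `delta_pp` percentage
#' points (proportionally within the matching and non-matching sets, so the
#' table still sums to 100). An effect that would push any abundance
#' negative errors.
#'
#' @param family `"H3.2"` or `"H4"`.
#' @param seed Integer seed.
#' @param sigma Replicate-to-replicate logistic-normal noise on the log
#'   scale (default 0.08, i.e. roughly 8 percent coefficient of variation).
#' @param design Cohort design tibble (`tissue`, `temperature`, `n`);
#'   default [study_design()].
#' @param profile `"study"` (default) or `"random"`.
#' @param n_proteoforms For random profiles, how many proteoforms to plant.
#' @param effects For random profiles, list of effect specs (see Details).
#' @param group_col Column the effects key on (default `"temperature"`).
#' @param n_tech_reps Technical replicates per biological sample (measured
#'   values are averaged downstream; default 1 generates biological
#'   replicates only).
#' @return List with `truth` (tibble `tissue`, `temperature`, `proteoform`,
#'   `abundance`) and `table` (long abundance table with `replicate`,
#'   `sample`, `tissue`, `temperature`).
#' @export
gen_proteoform_cohort <- function(family = "H3.2", seed = 1, sigma = 0.08,
                                  design = study_design(),
                                  profile = c("study", "random"),
                                  n_proteoforms = 20, effects = list(),
                                  group_col = "temperature",
                                  n_tech_reps = 1L) {
  profile <- match.arg(profile)
  backbone <- histone_backbone(family)
  .with_seed(.child_seed(seed, 1), {
    if (profile == "study") {
      truth <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
        study_profile(family, design$tissue[i], design$temperature[i]) |>
          mutate(tissue = design$tissue[i],
                 temperature = design$temperature[i])
      })
    } else {
      space <- enumerate_proteoforms(backbone)
      pick <- sample(nrow(space), n_proteoforms)
      base <- as.numeric(stats::rgamma(n_proteoforms, shape = 5))
      base <- base / sum(base) * 100
      truth <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
        tibble(proteoform = space$label[pick], abundance = base,
               tissue = design$tissue[i], temperature = design$temperature[i])
      })
      for (ef in effects) {
        rows <- truth[[group_col]] == ef$group
        sub <- truth[rows, ]
        q <- parse_notation(ef$mark, backbone)
        hit <- .labels_matching_query(sub$proteoform, q)[sub$proteoform]
        in_sum <- sum(sub$abundance[hit])
        out_sum <- sum(sub$abundance[!hit])
        if (in_sum == 0 || out_sum == 0) {
          abort("effect mark matches all or none of the planted proteoforms")
        }
        adj <- ifelse(hit,
                      sub$abundance * (1 + ef$delta_pp / in_sum),
                      sub$abundance * (1 - ef$delta_pp / out_sum))
        if (any(adj < 0)) abort("planted effect pushes an abundance below 0")
        truth$abundance[rows] <- adj
      }
    }

    table <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
      truth_i <- truth |>
        filter(.data$tissue == design$tissue[i],
               .data$temperature == design$temperature[i])
      purrr::map_dfr(seq_len(design$n[i]), function(r) {
        sample_id <- paste(design$tissue[i], design$temperature[i], r,
                           sep = "_")
        purrr::map_dfr(seq_len(max(1L, n_tech_reps)), function(t) {
          tibble(
            proteoform = truth_i$proteoform,
            abundance = .jitter_abundances(truth_i$abundance, sigma),
            replicate = paste0(sample_id, "_t", t),
            sample = sample_id,
            tissue = design$tissue[i],
            temperature = design$temperature[i]
          )
        })
      })
    })
    list(truth = truth, table = table)
  })
}

#' Simulate a top-down MS run from a truth table
#'
#' Places MS1 peaks at the theoretical m/z of each proteoform composition
#' across a charge-state envelope, with intensity proportional to planted
#' abundance, and emits one ETD MS2 scan per composition whose c/z fragment
#' peaks carry positional information: ions unique to an isomer get
#' intensity proportional to that isomer's abundance, shared ions to the
#' composition total. Mass accuracy is controlled by ppm jitter
#' (`ms1_ppm`, `frag_ppm`); intensities by a multiplicative CV.
#'
#' @param truth Tibble `proteoform`, `abundance` (percent, one run).
#' @param backbone The [histone_backbone()].
#' @param seed Integer seed.
#' @param charges Charge states of the MS1 envelope (defaults: 8-10 for the
#'   H3.2 GluC analyte, 9-15 for intact H4).
#' @param ms1_ppm,frag_ppm Gaussian m/z jitter, ppm (clamped at three
#'   standard deviations).
#' @param intensity_cv Multiplicative intensity noise.
#' @param metadata Named list attached to the run (family, replicate id...).
#' @return A `topdown_run`: list with `ms1` (tibble `mz`, `z`,
#'   `intensity`), `ms2` (list of scans with `precursor_mass` and
#'   `fragments`), `metadata`.
#' @export
gen_topdown_run <- function(truth, backbone, seed = 1, charges = NULL,
                            ms1_ppm = 1.0, frag_ppm = 2.5,
                            intensity_cv = 0.05, metadata = list()) {
  charges <- charges %||%
    if (backbone$family == "H4") 9:15 else 8:10
  .with_seed(.child_seed(seed, 2), {
    forms <- lapply(truth$proteoform, parse_notation, backbone = backbone)
    info <- tibble(
      label = truth$proteoform,
      abundance = truth$abundance,
      mass = vapply(forms, proteoform_mass, 0),
      composition = vapply(forms, .composition_key, "")
    )
    jitter_ppm <- function(m, ppm) {
      e <- rnorm(length(m), 0, ppm)
      e <- pmax(pmin(e, 3 * ppm), -3 * ppm)
      m * (1 + e * 1e-6)
    }
    env_w <- stats::dnorm(charges, mean = mean(charges),
                          sd = max(1, diff(range(charges)) / 4))
    env_w <- env_w / sum(env_w)

    comps <- info |>
      group_by(.data$composition) |>
      summarise(mass = .data$mass[1], abundance = sum(.data$abundance),
                .groups = "drop")
    ms1 <- purrr::map_dfr(seq_len(nrow(comps)), function(i) {
      tibble(
        mz = jitter_ppm(mz(comps$mass[i], charges), ms1_ppm),
        z = charges,
        intensity = comps$abundance[i] * env_w *
          exp(rnorm(length(charges), 0, intensity_cv))
      )
    })

    ms2 <- lapply(seq_len(nrow(comps)), function(i) {
      iso <- info[info$composition == comps$composition[i], ]
      ladders <- lapply(iso$label, function(lb) {
        generate_cz_ions(parse_notation(lb, backbone))
      })
      frag <- purrr::map_dfr(seq_along(ladders), function(j) {
        mutate(ladders[[j]], isomer = j)
      })
      frag$key <- paste0(frag$ion, frag$index)
      by_key <- frag |>
        group_by(.data$key) |>
        summarise(
          masses = list(.data$neutral_mass),
          isomers = list(.data$isomer),
          .groups = "drop"
        )
      peaks <- purrr::map_dfr(seq_len(nrow(by_key)), function(r) {
        ms <- by_key$masses[[r]]
        is_ <- by_key$isomers[[r]]
        grp <- round(ms, 6)
        tibble(mass = ms, isomer = is_, grp = grp) |>
          group_by(.data$grp) |>
          summarise(
            mass = .data$mass[1],
            intensity = sum(iso$abundance[.data$isomer]),
            .groups = "drop"
          ) |>
          select("mass", "intensity")
      })
      peaks <- peaks |>
        group_by(.data$mass) |>
        summarise(intensity = sum(.data$intensity), .groups = "drop")
      list(
        precursor_mass = comps$mass[i],
        fragments = tibble(
          mz = jitter_ppm(peaks$mass + .mass_const$proton, frag_ppm),
          z = 1L,
          intensity = peaks$intensity * exp(rnorm(nrow(peaks), 0,
                                                  intensity_cv))
        )
      )
    })

    structure(list(ms1 = ms1, ms2 = ms2,
                   metadata = c(list(family = backbone$family), metadata)),
              class = "topdown_run")
  })
}

#' @export
print.topdown_run <- function(x, ...) {
  cat("<topdown_run> ", x$metadata$family %||% "?", ": ",
      nrow(x$ms1), " MS1 peaks, ", length(x$ms2), " MS2 scans\n", sep = "")
  invisible(x)
}

#' Generate a consensome world with planted regulators
#'
#' Builds per-dataset gene peak-strength tables for a set of regulatory
#' nodes plus an "induced" gene set. Planted regulator nodes have their top
#' 5 percent of genes (the prospective HCT set) overlap the induced set at
#' `overlap_rate`; null nodes overlap at chance.
#'
#' @param seed Integer seed.
#' @param n_nodes Total nodes; the first `n_planted` are planted regulators.
#' @param n_planted Number of planted regulators.
#' @param universe_size Number of genes in the world.
#' @param n_datasets ChIP-Seq-like datasets per node.
#' @param geneset_size Size of the induced gene set.
#' @param overlap_rate Fraction of a planted node's HCT genes drawn from the
#'   induced set.
#' @return List: `strengths` (tibble `node`, `gene`, `dataset`,
#'   `peak_strength`), `gene_set` (induced genes), `universe` (all genes),
#'   `planted` (node ids).
#' @export
gen_consensome_world <- function(seed = 1, n_nodes = 60, n_planted = 1,
                                 universe_size = 2000, n_datasets = 3,
                                 geneset_size = 150, overlap_rate = 0.5) {
  .with_seed(.child_seed(seed, 3), {
    genes <- sprintf("g%05d", seq_len(universe_size))
    gene_set <- sample(genes, geneset_size)
    nodes <- sprintf("node%03d", seq_len(n_nodes))
    hct_n <- ceiling(universe_size * 0.05)
    strengths <- purrr::map_dfr(seq_len(n_nodes), function(i) {
      base <- matrix(runif(universe_size * n_datasets),
                     nrow = universe_size)
      if (i <= n_planted) {
        n_in <- round(hct_n * overlap_rate)
        top <- c(sample(gene_set, n_in),
                 sample(setdiff(genes, gene_set), hct_n - n_in))
        rows <- match(top, genes)
        base[rows, ] <- base[rows, ] + 2
      }
      tibble(
        node = nodes[i],
        gene = rep(genes, n_datasets),
        dataset = rep(paste0("ds", seq_len(n_datasets)), each = universe_size),
        peak_strength = as.vector(base)
      )
    })
    list(strengths = strengths, gene_set = gene_set, universe = genes,
         planted = nodes[seq_len(n_planted)])
  })
}

#' Generate a methylome cohort with expression coupling
#'
#' Simulates per-CpG methylated/unmethylated counts for promoters of
#' `n_regions` genes across two groups, with a fraction of planted
#' differentially methylated promoters, and a coupled expression table:
#' planted hypomethylated promoters carry negative-binomial expression
#' up-shifts at `coupled_log2fc` (hypermethylated ones the mirror
#' down-shift), null genes are uncoupled. Optionally writes
#' Bismark-coverage-format files, a BED annotation and a DEG CSV.
#'
#' @param seed Integer seed.
#' @param n_regions Number of genes/promoters.
#' @param n_planted Planted DM promoters (first `n_planted` genes;
#'   alternating hypo/hyper in ratio `hypo_fraction`).
#' @param hypo_fraction Fraction of planted regions that are hypomethylated
#'   in group B.
#' @param effect Methylation difference of planted regions, as a proportion
#'   (default 0.4 = 40 percentage points).
#' @param coverage Mean per-CpG read coverage.
#' @param cpg_per_region CpGs per promoter.
#' @param n_per_group Samples per group.
#' @param groups Names of the two groups (reference first).
#' @param coupled_log2fc Expression log2 fold change coupled to planted
#'   promoters (sign follows direction: hypo -> up).
#' @param nb_dispersion Negative-binomial size parameter of expression
#'   counts.
#' @param planted_base If non-NULL, baseline methylation proportion forced
#'   on planted regions (hypo regions start at `planted_base`, hyper
#'   regions at `1 - planted_base`), so large effects are not clipped.
#' @param dir If non-NULL, directory to write coverage/annotation/DEG files.
#' @return List: `calls` (CpG call tibble), `annotation`, `truth`, `deg`,
#'   and `files` (paths, when written).
#' @export
gen_methylome_cohort <- function(seed = 1, n_regions = 200, n_planted = 20,
                                 hypo_fraction = 0.7, effect = 0.4,
                                 coverage = 30, cpg_per_region = 12,
                                 n_per_group = 4, groups = c("TN", "SC"),
                                 coupled_log2fc = 1, nb_dispersion = 10,
                                 planted_base = NULL, dir = NULL) {
  stopifnot(length(groups) == 2)
  .with_seed(.child_seed(seed, 4), {
    genes <- sprintf("gene%04d", seq_len(n_regions))
    tss <- 5000 + (seq_len(n_regions) - 1) * 10000
    strand <- rep(c("+", "-"), length.out = n_regions)
    annotation <- tibble(
      gene = genes, chrom = "chrS",
      start = ifelse(strand == "+", tss, tss - 3000),
      end = ifelse(strand == "+", tss + 3000, tss),
      strand = strand
    )
    n_hypo <- round(n_planted * hypo_fraction)
    direction <- c(rep("hypo", n_hypo), rep("hyper", n_planted - n_hypo),
                   rep("none", n_regions - n_planted))
    base_p <- stats::rbeta(n_regions, 4, 4) * 0.6 + 0.2  # 0.2 .. 0.8
    if (!is.null(planted_base)) {
      base_p[direction == "hypo"] <- planted_base
      base_p[direction == "hyper"] <- 1 - planted_base
    }
    shift <- ifelse(direction == "hypo", -effect,
                    ifelse(direction == "hyper", effect, 0))
    p_b <- pmin(pmax(base_p + shift, 0.02), 0.98)
    truth <- tibble(gene = genes, direction = direction,
                    p_ref = base_p, p_alt = p_b)

    samples <- c(paste0(groups[1], "_", seq_len(n_per_group)),
                 paste0(groups[2], "_", seq_len(n_per_group)))
    sample_group <- rep(groups, each = n_per_group)

    calls <- purrr::map_dfr(seq_len(n_regions), function(i) {
      pos <- sort(tss[i] + sample.int(2000, cpg_per_region) - 1000L)
      purrr::map_dfr(seq_along(samples), function(s) {
        p <- if (sample_group[s] == groups[1]) base_p[i] else p_b[i]
        cov <- rnbinom(cpg_per_region, mu = coverage,
                       size = nb_dispersion) + 1L
        m <- rbinom(cpg_per_region, cov, p)
        tibble(sample = samples[s], group = sample_group[s],
               chrom = "chrS", pos = pos, strand = "+",
               meth = m, unmeth = cov - m)
      })
    })

    # expression counts coupled to the planted promoters
    mu_base <- stats::rlnorm(n_regions, log(500), 0.4)
    lfc <- ifelse(direction == "hypo", coupled_log2fc,
                  ifelse(direction == "hyper", -coupled_log2fc, 0))
    counts <- vapply(seq_along(samples), function(s) {
      mu <- if (sample_group[s] == groups[1]) mu_base else
        mu_base * 2^lfc
      rnbinom(n_regions, mu = mu, size = nb_dispersion * 5)
    }, numeric(n_regions))
    # DEG table emulating a negative-binomial differential test: the
    # simulation knows the true dispersion, so the likelihood-ratio test
    # uses the exact NB likelihood with known size (the group mean is the
    # mean MLE); real pipelines must estimate the dispersion instead
    a_idx <- sample_group == groups[1]
    size_expr <- nb_dispersion * 5
    nb_ll <- function(y, mu) {
      sum(stats::dnbinom(y, size = size_expr, mu = max(mu, 1e-8),
                         log = TRUE))
    }
    deg <- purrr::map_dfr(seq_len(n_regions), function(i) {
      ya <- counts[i, a_idx]; yb <- counts[i, !a_idx]
      lrt <- 2 * (nb_ll(ya, mean(ya)) + nb_ll(yb, mean(yb)) -
                    nb_ll(c(ya, yb), mean(c(ya, yb))))
      tibble(
        gene = genes[i],
        log2FC = log2((mean(yb) + 0.5) / (mean(ya) + 0.5)),
        p = stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
      )
    })
    deg$p_adj <- bh_adjust(deg$p)
    deg$direction <- ifelse(deg$log2FC >= 0, "up", "down")
    deg$p <- NULL

    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      cov_files <- vapply(samples, function(s) {
        d <- calls[calls$sample == s, ]
        path <- file.path(dir, paste0(s, ".synthetic.cov"))
        readr::write_tsv(
          tibble(chrom = d$chrom, start = d$pos, end = d$pos,
                 pct = round(100 * d$meth / (d$meth + d$unmeth), 6),
                 meth = d$meth, unmeth = d$unmeth),
          path, col_names = FALSE, progress = FALSE
        )
        path
      }, "")
      ann_path <- file.path(dir, "annotation.synthetic.bed")
      readr::write_tsv(
        tibble(chrom = annotation$chrom, start = annotation$start,
               end = annotation$end, name = annotation$gene, score = 0,
               strand = annotation$strand),
        ann_path, col_names = FALSE, progress = FALSE
      )
      deg_path <- file.path(dir, "deg.synthetic.csv")
      readr::write_csv(deg, deg_path, progress = FALSE)
      groups_path <- file.path(dir, "groups.synthetic.txt")
      writeLines(groups, groups_path)   # reference group first
      files <- list(coverage = cov_files, annotation = ann_path,
                    deg = deg_path, groups = groups_path)
    }
    list(calls = calls, annotation = annotation, truth = truth, deg = deg,
         files = files)
  })
}
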