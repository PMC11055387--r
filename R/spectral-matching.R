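# Theoretical ETD spectrum generation, MS1/MS2 matching, positional-isomer
# localization, and conversion of matched signal into percent-abundance
# tables.
#
# Ion chemistry: c and z-dot ions, with neutral c_i = sum(residues 1..i) +
# prefix PTM deltas + NH3 (17.026549) and z._j = M + 1.007825 - c_(n-j).
# The complementarity c_i + z._(n-i) = M + 1.007825 holds for every i.

#' Match configuration
#'
#' Holds the matching tolerances: the MS1 mass window in Da (default 3.4,
#' deliberately wide enough to span isotopologue and deamidation ambiguity,
#' so ambiguous composition hits are reported rather than dropped) and the
#' fragment tolerance in ppm for c/z ions (default 10.0).
#'
#' @param ms1_window MS1 window, Da.
#' @param fragment_tol Fragment tolerance, ppm.
#' @param min_site_determining_ions Minimum matched site-determining ions
#'   for an isomer to receive signal in a localized split (default 2: a
#'   single stray fragment never establishes a positional isomer).
#' @param ms1_accuracy Expected deconvoluted MS1 mass accuracy, Da.
#'   Candidates whose theoretical masses lie closer than this are treated
#'   as one isobar group whose composition is decided by MS2 fragment
#'   evidence, not by MS1 mass; the default 0.05 spans the 36-mDa
#'   acetyl-vs-trimethyl ambiguity.
#' @return A `match_config` list.
#' @export
match_config <- function(ms1_window = 3.4, fragment_tol = 10.0,
                         min_site_determining_ions = 2L,
                         ms1_accuracy = 0.05) {
  stopifnot(ms1_window > 0, fragment_tol > 0, ms1_accuracy > 0)
  structure(
    list(ms1_window = ms1_window, fragment_tol = fragment_tol,
         min_site_determining_ions = as.integer(min_site_determining_ions),
         ms1_accuracy = ms1_accuracy),
    class = "match_config"
  )
}

#' HPLC standard curves for histone mass estimation
#'
#' Linear curves relating offline HPLC peak area to micrograms of histone:
#' ug = (area - intercept) / slope. The shipped constants are H3: intercept
#' 2.6558, slope 14.221; H4: intercept 6.0114, slope 31.215.
#'
#' @param family `"H3"` or `"H4"`, or use `intercept`/`slope` directly.
#' @param intercept,slope Curve parameters overriding the family defaults.
#' @return A `standard_curve` list.
#' @export
standard_curve <- function(family = c("H3", "H4"), intercept = NULL,
                           slope = NULL) {
  if (is.null(intercept) || is.null(slope)) {
    family <- match.arg(family)
    defaults <- list(H3 = c(2.6558, 14.221), H4 = c(6.0114, 31.215))
    intercept <- intercept %||% defaults[[family]][1]
    slope <- slope %||% defaults[[family]][2]
  } else {
    family <- if (is.character(family)) family[1] else "custom"
  }
  stopifnot(slope > 0)
  structure(list(family = family, intercept = intercept, slope = slope),
            class = "standard_curve")
}

#' Micrograms of histone from an HPLC peak area
#'
#' Applies the linear standard curve; areas below the intercept clamp to
#' zero with a warning (a peak smaller than the blank carries no mass
#' estimate).
#'
#' @param area Peak area (>= 0).
#' @param curve A [standard_curve()].
#' @return Micrograms.
#' @examples
#' micrograms_from_area(16.8768, standard_curve("H3"))
#' @export
micrograms_from_area <- function(area, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(area < 0)) abort("peak area must be non-negative")
  out <- (area - curve$intercept) / curve$slope
  if (any(out < 0)) {
    warn("peak area below curve intercept; clamped to 0 ug")
    out <- pmax(out, 0)
  }
  out
}

#' Theoretical c/z-dot fragment ladder of a proteoform
#'
#' Neutral fragment masses over the analyte span: c_i ions for i = 1 ..
#' n - 1 (the full-length "c_n" is excluded) and the complementary z-dot
#' ions.
#'
#' @param p A [proteoform()].
#' @return Tibble with `ion` (`"c"`/`"z"`), `index`, `neutral_mass`.
#' @export
generate_cz_ions <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  bb <- p$backbone
  span <- bb$analyte_span
  res <- strsplit(bb$residues, "")[[1]][span[1]:span[2]]
  n <- length(res)
  if (n < 2) abort("analyte must have length >= 2")
  deltas <- numeric(n)
  nterm_delta <- 0
  for (i in seq_len(nrow(p$ptms))) {
    s <- p$ptms$site[i]
    d <- .ptm_delta[[p$ptms$kind[i]]]
    if (s == 0L) nterm_delta <- nterm_delta + d
    else deltas[s - span[1] + 1L] <- deltas[s - span[1] + 1L] + d
  }
  prefix <- cumsum(.residue_mass[res] + deltas)
  m <- prefix[n] + .mass_const$water + nterm_delta
  c_ions <- prefix[seq_len(n - 1)] + .mass_const$nh3 + nterm_delta
  z_ions <- m + .mass_const$hydrogen - c_ions
  tibble(
    ion = rep(c("c", "z"), each = n - 1),
    index = c(seq_len(n - 1), rev(seq_len(n - 1))),
    neutral_mass = unname(c(c_ions, z_ions))
  )
}

#' Match an observed MS1 neutral mass against candidate proteoforms
#'
#' Returns every candidate whose theoretical mass lies within the MS1
#' window, grouped by composition: positional isomers share a composition
#' (identical PTM-kind counts) and are mass-identical, so they form one
#' isomer group to be resolved by MS2 evidence.
#'
#' @param observed_mass Observed neutral monoisotopic mass, Da.
#' @param candidates Candidate tibble from [enumerate_proteoforms()], or any
#'   tibble with `label`, `mass`, `composition`.
#' @param cfg A [match_config()].
#' @return Tibble of matching candidates with `mass_error` (observed -
#'   theoretical), sorted by |error|; zero rows if nothing matches.
#' @export
match_ms1 <- function(observed_mass, candidates, cfg = match_config()) {
  if (nrow(candidates) == 0) abort("empty candidate set")
  hits <- candidates |>
    mutate(mass_error = observed_mass - .data$mass) |>
    filter(abs(.data$mass_error) <= cfg$ms1_window) |>
    arrange(abs(.data$mass_error))
  hits
}

# Per-composition isomer ladders, cached per call site. Returns list of
# tibbles keyed by label.
.isomer_ladders <- function(isomer_ptms, backbone) {
  lapply(isomer_ptms, function(pt) {
    generate_cz_ions(proteoform(backbone, pt))
  })
}

# Neutralize observed fragment peaks (m/z, z) and match against a set of
# theoretical neutral masses at a ppm tolerance. Returns the summed
# intensity of matched peaks and the number of matches.
.match_fragments <- function(frag_mass, frag_int, theo_mass, tol_ppm) {
  if (length(theo_mass) == 0 || length(frag_mass) == 0) {
    return(list(intensity = 0, n = 0L, matched = logical(length(frag_mass))))
  }
  matched <- vapply(frag_mass, function(fm) {
    any(abs(fm - theo_mass) / theo_mass * 1e6 <= tol_ppm)
  }, TRUE)
  list(intensity = sum(frag_int[matched]), n = sum(matched),
       matched = matched)
}

#' Localize positional isomers and split shared MS1 signal
#'
#' Given an MS2 scan and a group of positional isomers, matches observed
#' fragments to the union of the isomers' theoretical c/z masses within the
#' ppm tolerance and attributes intensity to isomers. Site-determining ions
#' -- those whose theoretical mass differs between isomers -- carry the
#' positional information: with two isomers and disjoint site-determining
#' evidence the split is exactly proportional to summed site-determining
#' intensity. In general (several isomers sharing partial ladder overlap)
#' the attribution is the maximum-likelihood mixture fit under a Poisson
#' intensity model, computed by EM over the incidence of theoretical masses
#' in each isomer's ladder; theoretical ions with no observed intensity
#' count as zeros, so isomers without supporting evidence shrink to
#' fraction 0. When no site-determining mass is matched at all, fractions
#' are returned as 0 with `unlocalized = TRUE`.
#'
#' @param scan A scan: list with `fragments`, a tibble of `mz`, `z`,
#'   `intensity`.
#' @param isomers Tibble with `label` and list-column `ptms` (as produced by
#'   [enumerate_proteoforms()]), all one composition.
#' @param backbone The [histone_backbone()].
#' @param cfg A [match_config()].
#' @param ladders Optional precomputed list of fragment ladders (one per
#'   isomer row), to avoid regeneration in tight loops.
#' @return Tibble: `label`, `fraction`, `sd_intensity`, `n_sd_matched`,
#'   `unlocalized`.
#' @export
localize_and_split <- function(scan, isomers, backbone,
                               cfg = match_config(), ladders = NULL) {
  stopifnot(nrow(isomers) >= 1)
  frag <- scan$fragments
  if (is.null(frag) || nrow(frag) == 0) {
    abort("unidentified scan: no fragment peaks")
  }
  fm <- neutral_mass(frag$mz, frag$z)
  if (nrow(isomers) == 1) {
    return(tibble(label = isomers$label, fraction = 1,
                  sd_intensity = sum(frag$intensity),
                  n_sd_matched = NA_integer_, unlocalized = FALSE))
  }
  ladders <- ladders %||% .isomer_ladders(isomers$ptms, backbone)
  n_iso <- nrow(isomers)

  # union of theoretical masses; incidence matrix A[row, isomer]
  all_mass <- sort(unique(round(unlist(
    lapply(ladders, function(ld) ld$neutral_mass)
  ), 5)))
  A <- vapply(ladders, function(ld) {
    all_mass %in% round(ld$neutral_mass, 5)
  }, logical(length(all_mass)))
  if (is.null(dim(A))) A <- matrix(A, nrow = length(all_mass))

  # theoretical ions closer together than 1.5x the matching tolerance
  # cannot be told apart: a fragment whose mass error approaches the
  # tolerance can land nearer the wrong row (e.g. +ac vs +me3 prefixes,
  # 36 mDa apart, on fragments above ~2.4 kDa at 10 ppm). Merge such rows
  # into one shared by both isomer sets, so only reliably resolvable ions
  # discriminate.
  tol_da <- 1.5 * cfg$fragment_tol * 1e-6 * all_mass
  cl <- cumsum(c(0, diff(all_mass)) > tol_da)
  if (any(duplicated(cl))) {
    A <- rowsum(A + 0, cl) > 0
    all_mass <- as.vector(tapply(all_mass, cl, mean))
  }
  shared <- rowSums(A) == n_iso          # non-site-determining rows

  # observed intensity per theoretical row (nearest match within tolerance)
  obs <- numeric(length(all_mass))
  n_matched_row <- integer(length(all_mass))
  for (j in seq_along(fm)) {
    d <- abs(fm[j] - all_mass) / all_mass * 1e6
    r <- which.min(d)
    if (d[r] <= cfg$fragment_tol) {
      obs[r] <- obs[r] + frag$intensity[j]
      n_matched_row[r] <- n_matched_row[r] + 1L
    }
  }
  if (all(obs == 0)) abort("unidentified scan: no fragment within tolerance")

  sd_matched <- obs > 0 & !shared
  n_sd <- vapply(seq_len(n_iso), function(i) sum(sd_matched & A[, i]), 0L)
  eligible <- n_sd >= cfg$min_site_determining_ions
  if (!any(sd_matched) || !any(eligible)) {
    return(tibble(label = isomers$label, fraction = 0,
                  sd_intensity = 0, n_sd_matched = n_sd,
                  unlocalized = TRUE))
  }
  # isomers below the site-determining evidence floor take no signal
  A <- A[, eligible, drop = FALSE]

  # Poisson-mixture EM on rows (zeros included via the denominator)
  n_iso_fit <- sum(eligible)
  w <- rep(1 / n_iso_fit, n_iso_fit)
  n_rows_i <- colSums(A)
  Anum <- matrix(as.numeric(A), nrow = length(all_mass))
  for (it in seq_len(200)) {
    lambda <- as.vector(Anum %*% w)
    ratio <- ifelse(lambda > 0, obs / lambda, 0)
    w_new <- w * as.vector(t(Anum) %*% ratio) / n_rows_i
    if (sum(w_new) == 0) break
    if (max(abs(w_new - w)) < 1e-12 * max(sum(w_new), 1)) {
      w <- w_new
      break
    }
    w <- w_new
  }
  frac_fit <- if (sum(w) > 0) w / sum(w) else rep(0, n_iso_fit)
  frac_fit[frac_fit < 1e-6] <- 0
  if (sum(frac_fit) > 0) frac_fit <- frac_fit / sum(frac_fit)
  lambda <- as.vector(Anum %*% w)
  sd_fit <- vapply(seq_len(n_iso_fit), function(i) {
    rows <- sd_matched & A[, i] & lambda > 0
    sum(obs[rows] * (w[i] / lambda[rows]))
  }, 0)
  fractions <- sd_int <- numeric(n_iso)
  fractions[eligible] <- frac_fit
  sd_int[eligible] <- sd_fit
  tibble(label = isomers$label, fraction = fractions,
         sd_intensity = sd_int, n_sd_matched = n_sd, unlocalized = FALSE)
}

#' Quantify one top-down run into a percent-abundance table row set
#'
#' MS1 peaks are deconvoluted to neutral masses (peaks carrying an explicit
#' charge are converted directly) and matched against the candidate space
#' within the MS1 window. Candidates are clustered into isobar groups by
#' single linkage at the MS1 mass accuracy: exactly isobaric compositions
#' (me1+me2 vs me3) and near-isobars the MS1 mass cannot separate (one
#' acetyl vs one trimethyl, 36 mDa) join the positional isomers of one
#' group, because within the wide MS1 window composition identity is an MS2
#' question, not an MS1 one. Each group's pooled MS1 intensity is then
#' split over all its member proteoforms by [localize_and_split()] on the
#' pooled fragments of its scans -- members without fragment support shrink
#' to zero -- and the result is normalized so the family sums to 100
#' percent. Peaks for which several isobar groups fell inside the window
#' are recorded as ambiguous rather than dropped.
#'
#' @param run A `topdown_run` (see [read_peaklist()] / [gen_topdown_run()]).
#' @param backbone The [histone_backbone()].
#' @param cfg A [match_config()].
#' @param candidates Candidate proteoform space; defaults to the full
#'   enumeration of the backbone.
#' @return List with `table` (tibble `proteoform`, `abundance`, plus run
#'   metadata), `ambiguous` (MS1 peaks with >1 composition in the window),
#'   and `unlocalized` (composition groups whose evidence was shared).
#' @export
quantify_run <- function(run, backbone, cfg = match_config(),
                         candidates = NULL) {
  candidates <- candidates %||% enumerate_proteoforms(backbone)
  ms1 <- run$ms1
  stopifnot(all(c("intensity") %in% names(ms1)))
  obs_mass <- if ("neutral_mass" %in% names(ms1) &&
                  any(!is.na(ms1$neutral_mass))) {
    ms1$neutral_mass
  } else {
    neutral_mass(ms1$mz, ms1$z)
  }

  # isobar groups by single linkage at the MS1 accuracy: candidate masses
  # closer than ms1_accuracy chain into one group (positional isomers,
  # exact isobars, and 36-mDa ac/me3 neighbours); distinct groups are at
  # least one methyl step apart and unambiguous at sub-Da accuracy
  ord <- order(candidates$mass)
  gap <- c(0, diff(candidates$mass[ord]))
  grp_id <- cumsum(gap > cfg$ms1_accuracy)
  candidates$isobar <- NA_character_
  candidates$isobar[ord] <- sprintf("iso%04d", grp_id)
  comp_tbl <- candidates |>
    group_by(.data$isobar) |>
    summarise(mass = mean(.data$mass), lo = min(.data$mass),
              hi = max(.data$mass), .groups = "drop")

  # fragment ladders computed once per candidate
  ladder_cache <- new.env(parent = emptyenv())
  get_ladders <- function(iso) {
    lapply(seq_len(nrow(iso)), function(i) {
      lb <- iso$label[i]
      if (is.null(ladder_cache[[lb]])) {
        ladder_cache[[lb]] <- generate_cz_ions(proteoform(backbone,
                                                          iso$ptms[[i]]))
      }
      ladder_cache[[lb]]
    })
  }

  scans <- run$ms2
  scan_masses <- if (length(scans)) {
    vapply(scans, function(s) s$precursor_mass, 0)
  } else numeric()

  assign_rows <- purrr::map_dfr(seq_along(obs_mass), function(i) {
    err <- pmax(comp_tbl$lo - obs_mass[i], obs_mass[i] - comp_tbl$hi, 0)
    inside <- which(err <= cfg$ms1_window)
    if (length(inside) == 0) return(tibble())
    pick <- inside[which.min(err[inside])]
    tibble(peak = i, isobar = comp_tbl$isobar[pick],
           intensity = ms1$intensity[i],
           ambiguous = length(inside) > 1,
           n_candidates = length(inside))
  })
  if (nrow(assign_rows) == 0 || sum(assign_rows$intensity) == 0) {
    abort("zero total matched MS1 intensity in run")
  }

  comp_int <- assign_rows |>
    group_by(.data$isobar) |>
    summarise(intensity = sum(.data$intensity), .groups = "drop")

  unlocalized <- character()
  rows <- purrr::map_dfr(seq_len(nrow(comp_int)), function(i) {
    grp <- comp_int$isobar[i]
    iso <- candidates[candidates$isobar == grp, ]
    if (nrow(iso) == 1) {
      return(tibble(proteoform = iso$label,
                    abundance = comp_int$intensity[i]))
    }
    # localize every scan targeting this isobar group separately -- each
    # scan is one precursor selection, and keeping scans apart avoids the
    # chimeric-pair ambiguity that pooling their fragments would create --
    # then aggregate the per-scan splits weighted by scan intensity
    s_idx <- which(scan_masses >= min(iso$mass) - cfg$ms1_accuracy &
                     scan_masses <= max(iso$mass) + cfg$ms1_accuracy)
    if (length(s_idx)) {
      lads <- get_ladders(iso)
      agg <- numeric(nrow(iso))
      any_localized <- FALSE
      for (s in s_idx) {
        split <- tryCatch(
          localize_and_split(scans[[s]], iso, backbone, cfg, ladders = lads),
          error = function(e) NULL
        )
        if (is.null(split)) next
        if (!all(split$unlocalized)) {
          any_localized <- TRUE
          agg <- agg + sum(scans[[s]]$fragments$intensity) * split$fraction
        }
      }
      if (!any_localized || sum(agg) == 0) {
        unlocalized <<- c(unlocalized, grp)
        # evidence entirely shared: spread equally but flag the group
        agg <- rep(1, nrow(iso))
      }
      return(tibble(proteoform = iso$label,
                    abundance = comp_int$intensity[i] * agg / sum(agg)))
    }
    unlocalized <<- c(unlocalized, grp)
    tibble(proteoform = iso$label,
           abundance = comp_int$intensity[i] / nrow(iso))
  })

  tab <- rows |>
    group_by(.data$proteoform) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    filter(.data$abundance > 0) |>
    mutate(abundance = .data$abundance / sum(.data$abundance) * 100)
  meta <- run$metadata %||% list()
  for (nm in names(meta)) tab[[nm]] <- meta[[nm]]
  list(
    table = tab,
    ambiguous = filter(assign_rows, .data$ambiguous),
    unlocalized = unlocalized
  )
}
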