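#' @importFrom rlang .data abort warn inform %||% := syms
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols distinct across all_of any_of rename
#' @importFrom stats median rnorm runif rbinom rnbinom setNames
#' @importFrom utils head combn
NULL

# Monoisotopic constants (Da). The proton mass is used for m/z arithmetic;
# atomic hydrogen enters the c/z fragment complementarity relation.
.mass_const <- list(
  proton   = 1.007276,
  hydrogen = 1.007825,
  water    = 18.010565,
  nh3      = 17.026549
)

# Monoisotopic residue (amino-acid minus water) masses.
.residue_mass <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

# PTM mass deltas. Acetylation and trimethylation differ by only 0.03639 Da,
# which is why MS2 evidence, not MS1 mass alone, settles composition calls.
# Phosphorylation is recognized so that labels mentioning it parse, but no
# default backbone site allows it.
.ptm_delta <- c(
  ac  = 42.010565,
  me1 = 14.015650,
  me2 = 28.031300,
  me3 = 42.046950,
  ph  = 79.966331
)

#' Monoisotopic PTM mass deltas
#'
#' @return Named numeric vector of mass deltas in Da for the recognized PTM
#'   kinds (`ac`, `me1`, `me2`, `me3`, `ph`).
#' @export
ptm_masses <- function() .ptm_delta

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "histoform")
  if (!nzchar(path)) {
    # during development the package may be loaded from source
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) abort(paste0("cannot find extdata file ", file))
  path
}

.read_backbone_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  out <- list()
  for (i in seq_along(hdr)) {
    end <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    fields <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    attrs <- strsplit(fields[-1], "=")
    attrs <- setNames(
      vapply(attrs, `[`, "", 2),
      vapply(attrs, `[`, "", 1)
    )
    out[[fields[1]]] <- list(
      residues = paste(lines[(hdr[i] + 1):end], collapse = ""),
      analyte  = as.integer(strsplit(attrs[["analyte"]], "-")[[1]]),
      n_term_ac_fixed = identical(attrs[["nterm_ac"]], "fixed")
    )
  }
  out
}

#' Histone backbone definition
#'
#' Loads the mature-chain sequence (initiator Met removed), the measured
#' analyte span, and the table of modifiable sites for a histone family.
#' Residue numbering is 1-based on the mature chain, so K9 is the ninth
#' mature residue, matching histone-field convention. Site index 0 denotes
#' the protein N-terminus. For H4 the N-terminal acetylation is fixed: it is
#' present on every proteoform and is omitted from canonical labels. The H3.2
#' analyte is the GluC N-terminal peptide, residues 1-50 (cleavage C-terminal
#' to Glu50).
#'
#' Definitions are read from editable files under `inst/extdata`
#' (`histone_backbones.fasta`, `histone_sites.tsv`); alternative files may be
#' supplied to model other variants or site lists.
#'
#' @param family `"H3.2"` or `"H4"` (or any family present in the files).
#' @param fasta,sites Optional paths overriding the shipped definitions.
#' @param analyte_span Optional integer length-2 vector overriding the
#'   measured span recorded in the FASTA header.
#' @return An object of class `histone_backbone`: a list with `family`,
#'   `residues`, `analyte_span`, `sites` (tibble of `site`, `kinds`),
#'   and `n_term_ac_fixed`.
#' @examples
#' bb <- histone_backbone("H4")
#' bb$analyte_span
#' @export
histone_backbone <- function(family, fasta = NULL, sites = NULL,
                             analyte_span = NULL) {
  fasta <- fasta %||% .extdata("histone_backbones.fasta")
  sites <- sites %||% .extdata("histone_sites.tsv")
  defs <- .read_backbone_fasta(fasta)
  if (!family %in% names(defs)) {
    abort(paste0("unknown histone family '", family, "'"))
  }
  def <- defs[[family]]
  site_tbl <- readr::read_tsv(sites, show_col_types = FALSE, progress = FALSE)
  site_tbl <- site_tbl[site_tbl$family == family, c("site_index", "allowed_kinds")]
  site_tbl <- tibble(
    site  = as.integer(site_tbl$site_index),
    kinds = strsplit(site_tbl$allowed_kinds, ",")
  )
  span <- as.integer(analyte_span %||% def$analyte)
  nres <- nchar(def$residues)
  stopifnot(length(span) == 2, span[1] >= 1, span[2] <= nres)
  res_letters <- strsplit(def$residues, "")[[1]]
  bad <- site_tbl$site > 0 & res_letters[pmax(site_tbl$site, 1)] != "K"
  if (any(bad)) abort("modifiable side-chain sites must be lysines")
  structure(
    list(
      family = family,
      residues = def$residues,
      analyte_span = span,
      sites = site_tbl,
      n_term_ac_fixed = def$n_term_ac_fixed
    ),
    class = "histone_backbone"
  )
}

#' @export
print.histone_backbone <- function(x, ...) {
  cat("<histone_backbone> ", x$family, ": ", nchar(x$residues),
      " aa mature chain, analyte ", x$analyte_span[1], "-", x$analyte_span[2],
      if (x$n_term_ac_fixed) ", fixed N-terminal ac" else "", "\n", sep = "")
  invisible(x)
}

.allowed_kinds <- function(backbone, site) {
  i <- match(site, backbone$sites$site)
  if (is.na(i)) return(character())
  backbone$sites$kinds[[i]]
}

#' Construct a proteoform
#'
#' A proteoform is one chemically defined histone molecule: a backbone plus
#' the exact co-occurring set of PTMs. At most one PTM may occupy a site and
#' every (site, kind) pair must be allowed on the backbone. If the backbone
#' carries a fixed N-terminal acetylation it is added implicitly.
#'
#' @param backbone A [histone_backbone()].
#' @param ptms Data frame with columns `site` (integer, 0 = N-terminus) and
#'   `kind` (`"ac"`, `"me1"`, `"me2"`, `"me3"`); may be empty.
#' @return Object of class `proteoform`.
#' @examples
#' bb <- histone_backbone("H4")
#' proteoform(bb, data.frame(site = 20, kind = "me2"))
#' @export
proteoform <- function(backbone, ptms = NULL) {
  stopifnot(inherits(backbone, "histone_backbone"))
  if (is.null(ptms) || nrow(ptms) == 0) {
    ptms <- tibble(site = integer(), kind = character())
  }
  ptms <- tibble(site = as.integer(ptms$site), kind = as.character(ptms$kind))
  if (backbone$n_term_ac_fixed && !0L %in% ptms$site) {
    ptms <- bind_rows(tibble(site = 0L, kind = "ac"), ptms)
  }
  if (anyDuplicated(ptms$site)) {
    abort("duplicate site: at most one PTM per site on a proteoform")
  }
  for (i in seq_len(nrow(ptms))) {
    ok <- ptms$kind[i] %in% .allowed_kinds(backbone, ptms$site[i])
    if (!ok) {
      abort(paste0("PTM ", ptms$kind[i], " not allowed at site ",
                   ptms$site[i], " on ", backbone$family))
    }
  }
  ptms <- ptms[order(ptms$site), ]
  structure(list(backbone = backbone, ptms = ptms), class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat("<proteoform> ", x$backbone$family, " ", format_notation(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a proteoform
#'
#' Sum of residue masses over the measured analyte span, plus water, plus the
#' mass deltas of all PTMs (including a fixed N-terminal acetylation).
#'
#' @param p A [proteoform()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' bb <- histone_backbone("H4")
#' proteoform_mass(proteoform(bb, data.frame(site = 20, kind = "me2")))
#' @export
proteoform_mass <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  bb <- p$backbone
  res <- strsplit(bb$residues, "")[[1]][bb$analyte_span[1]:bb$analyte_span[2]]
  if (any(!res %in% names(.residue_mass))) {
    abort(paste0("unknown residue letter(s): ",
                 paste(unique(res[!res %in% names(.residue_mass)]), collapse = "")))
  }
  sum(.residue_mass[res]) + .mass_const$water + sum(.ptm_delta[p$ptms$kind])
}

#' Count modification groups on a proteoform
#'
#' Methylation states contribute their methyl-group count (me1/me2/me3 = 1/2/3
#' methyl groups). N-terminal acetylation counts toward the total acetyl count
#' but not the side-chain count; abundance-weighted acetyl loads use the
#' side-chain count by default.
#'
#' @param p A [proteoform()].
#' @return One-row tibble with `n_acetyl_side_chain`, `n_acetyl_total`,
#'   `n_methyl_groups`.
#' @export
modification_counts <- function(p) {
  stopifnot(inherits(p, "proteoform"))
  ac_side <- sum(p$ptms$kind == "ac" & p$ptms$site > 0)
  ac_tot  <- sum(p$ptms$kind == "ac")
  me <- c(me1 = 1L, me2 = 2L, me3 = 3L)
  n_me <- sum(me[p$ptms$kind[p$ptms$kind %in% names(me)]])
  tibble(
    n_acetyl_side_chain = ac_side,
    n_acetyl_total = ac_tot,
    n_methyl_groups = as.integer(n_me %||% 0L)
  )
}

#' Mass-to-charge and neutral-mass conversion
#'
#' `mz()` computes (M + z * 1.007276) / z for a neutral mass M and positive
#' charge z; `neutral_mass()` inverts it.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param z Positive integer charge.
#' @return m/z (or neutral mass) as numeric.
#' @examples
#' mz(11193.8565, 15)
#' neutral_mass(mz(500, 2), 2)
#' @export
mz <- function(mass, z) {
  if (any(z <= 0)) abort("charge z must be a positive integer")
  (mass + z * .mass_const$proton) / z
}

#' @rdname mz
#' @param m_over_z Observed m/z.
#' @export
neutral_mass <- function(m_over_z, z) {
  if (any(z <= 0)) abort("charge z must be a positive integer")
  m_over_z * z - z * .mass_const$proton
}

# Enumerate the full combinatorial proteoform space of a backbone: every
# assignment of an allowed kind (or none) to each variable site. Returns one
# row per proteoform with its label, mass and composition key (PTM kind
# counts) -- positional isomers share a composition key and hence a mass.
#' Enumerate all proteoforms of a backbone
#'
#' Expands every combination of allowed PTM states over the backbone's
#' variable sites (H4: 128 proteoforms; H3.2 analyte: 3200). Used as the
#' default MS1 candidate set and for containment-query bookkeeping.
#'
#' @param backbone A [histone_backbone()].
#' @return Tibble with `label`, `mass`, `composition` (kind-count key, e.g.
#'   `"ac2.me3x1"`), `n_ptms`, and a list-column `ptms`.
#' @export
enumerate_proteoforms <- function(backbone) {
  var_sites <- backbone$sites[backbone$sites$site > 0 |
                                !backbone$n_term_ac_fixed, ]
  states <- lapply(seq_len(nrow(var_sites)), function(i) {
    c("", var_sites$kinds[[i]])
  })
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  names(grid) <- as.character(var_sites$site)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    kinds <- unlist(grid[i, ], use.names = TRUE)
    keep <- nzchar(kinds)
    tibble(site = as.integer(names(kinds)[keep]), kind = unname(kinds[keep]))
  })
  forms <- lapply(rows, function(pt) proteoform(backbone, pt))
  tibble(
    label = vapply(forms, format_notation, ""),
    mass = vapply(forms, proteoform_mass, 0),
    composition = vapply(forms, .composition_key, ""),
    n_ptms = vapply(forms, function(p) nrow(p$ptms), 0L),
    ptms = lapply(forms, `[[`, "ptms")
  )
}

# Composition key: counts of each side-chain-visible kind. Proteoforms with
# the same key are positional isomers and are mass-identical.
.composition_key <- function(p) {
  k <- table(factor(p$ptms$kind, levels = names(.ptm_delta)))
  paste0(names(k)[k > 0], k[k > 0], collapse = ".")
}
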