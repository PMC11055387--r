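---
title: "Quantitative histone proteoform analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative histone proteoform analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoform)
library(dplyr)
```

# The measurement problem

A histone proteoform is one chemically defined molecule: the backbone plus
the exact set of post-translational modifications (PTMs) it carries in cis.
Top-down mass spectrometry measures intact proteoforms, so the percent
abundance of every modification *combination* is observable — not only the
marginal occupancy of single marks, as in bottom-up workflows. histoform
implements the quantitative core of such an analysis for histones H4
(intact, 102 residues, fixed N-terminal acetylation) and H3.2 (the GluC
N-terminal peptide, residues 1–50, released by cleavage C-terminal to
Glu50; the measured MS1 window of 585–640 m/z at charges 8–10 corresponds
to this analyte).

The modeled site space follows the standard murine histone PTM repertoire:
H4 — variable K5ac, K8ac, K12ac, K16ac, K20me1/2/3, K31ac over a fixed
N-terminal acetylation; H3.2 — K4me1/2/3, K9ac/me1/2/3, K14ac, K18ac,
K23ac, K27ac/me1/2/3, K36me1/2/3. Enumerating one state (or none) per site
gives 128 H4 and 3200 H3.2 candidate proteoforms. Site tables and
sequences are shipped as editable text under `inst/extdata`, so other
variants or site lists can be modeled without code changes.

Phosphorylation is recognized by the parser (so labels mentioning it are
readable) but no default site allows it: the workflows this package
models report zero phosphorylation on these analytes.

# Notation

Angle brackets denote an exact state: `<K9me2K27me1>` is a molecule with
exactly those two marks. Curly brackets denote containment: `{K9me2}` sums
every proteoform carrying K9me2. Queries additionally support disjunction
(`{K9me2/3}`) and explicit absence (`{K9un}`). The fully unmodified
molecule is written `<un>`, a canonical token of this package (the
literature has no notation for it). Because H4's N-terminal acetylation is
fixed, it is implied on every H4 proteoform and omitted from canonical
labels; `N-ac` is accepted on input.

# Mass arithmetic and theoretical spectra

Masses are monoisotopic throughout: residue masses from the standard
table, water 18.010565, proton 1.007276 for m/z, and PTM deltas ac
42.010565, me1 14.015650, me2 28.031300, me3 42.046950 Da. ETD produces
c and z• ions; we generate neutral ladders as

- c_i = Σ residues(1..i) + prefix PTM deltas + 17.026549 (NH3), i < n
- z•_j = M + 1.007825 − c_(n−j)

so c_i + z•_(n−i) = M + 1.007825 for every i, a property the test suite
asserts. Ion chemistry is stated explicitly because published tolerances
("10 ppm for c and z fragment ions") leave it implicit.

A documented curiosity of the source data this package emulates: one
figure prints an 11,193.8565 Da species as "761.2961 m/z, charge +15",
which is not consistent with (M + 15H)/15 = 747.2646. `mz()` implements
the standard relation; both numbers are recorded here and the arithmetic
one is the tested behavior.

# Matching and positional-isomer quantitation

Matching uses the conventional tolerances: a 3.4 Da MS1 window and 10 ppm
for fragments (`match_config()`). The MS1 window is deliberately far wider
than instrument accuracy — it spans isotopologue and deamidation
ambiguity — so within it, composition identity is an MS2 question. Three
consequences drive the design of `quantify_run()`:

1. **Isobar groups.** Candidates are clustered by single linkage at the
   deconvoluted MS1 accuracy (`ms1_accuracy`, default 0.05 Da). This pools
   positional isomers (exactly mass-identical), exactly isobaric
   compositions (me1+me2 = me3 to the microdalton), and the 36-mDa
   acetyl-vs-trimethyl neighbors. MS1 peak intensity is aggregated per
   group; distinct groups are at least one methyl step (~14 Da) apart and
   unambiguous.
2. **Per-scan localization.** Each MS2 scan is one precursor selection.
   Scans targeting a group are localized *separately* and the splits
   aggregated with scan-intensity weights. Pooling fragments across scans
   would create chimeric-pair ambiguities (two different two-proteoform
   mixtures whose fragment-mass unions coincide); per-scan attribution
   avoids that failure mode wherever the acquisition separated the
   precursors.
3. **Fragment attribution by maximum likelihood.** Within a scan,
   `localize_and_split()` builds the union of the group's theoretical c/z
   masses, merges theoretical ions closer than 1.5× the fragment
   tolerance (such ions cannot be reliably told apart; for the 36-mDa
   ac/me3 spacing this happens above ~2.4 kDa at 10 ppm), matches observed
   fragments to the nearest surviving row, and fits mixture weights by EM
   under a Poisson intensity model in which each isomer spreads its
   intensity uniformly over its ladder. Theoretical ions with no observed
   intensity count as zeros, so candidates without supporting evidence
   shrink to zero weight. With two isomers and disjoint site-determining
   ions this reduces exactly to allocation proportional to summed
   site-determining intensity. An isomer must additionally match at least
   `min_site_determining_ions` (default 2) site-determining ions to
   receive any signal: a single stray fragment never establishes a
   positional isomer. If no site-determining mass is matched at all the
   group is flagged unlocalized and spread uniformly rather than silently
   dropped.

Quantified abundances are the group MS1 intensities times localization
fractions, normalized to 100% per histone family. Under the package's own
simulated acquisition model (charge envelopes 9–15 for H4, 8–10 for H3.2;
1 ppm MS1 and 2.5 ppm fragment jitter; 5% intensity CV) this recovers
planted 5–30-proteoform mixtures with identification recall ≥ 0.95 and
mean absolute abundance error under 2 percentage points, and splits 50:50
positional-isomer pairs within ±2 points — the test suite and acceptance
script recompute both. What passing these tests does *not* show: real
spectra add co-isolation chimeras the instrument did not separate,
incomplete fragmentation, isotopic-envelope errors and retention-time
effects, none of which the generator emulates.

# The proteoform algebra

On a percent-abundance table (rows = proteoform × replicate, summing to
100 per replicate) the package provides exact (`abundance_exact`) and
containment (`abundance_containing`) marginals, bulk acetylation
(`any_acetyl`, side-chain acetyls only by default — the fixed H4
N-terminal acetyl would otherwise add a constant), k-PTM combination
enumeration, and the modification load: Σ abundance_i × n_groups_i / 100,
the average number of acetyl or methyl groups per molecule (me2 counts 2
methyl groups, me3 counts 3).

Two change metrics are always reported together. The percentage-point
difference (pp) is the absolute scale: because abundances are percent of
total histone, a pp difference reads directly as the share of the genome's
nucleosomes that changed state. The fold change is the relative scale. A
mark going from 50% to 70% of the genome changes a fifth of the genome
yet is only 1.4-fold — under a |1.5| fold-change cutoff it would vanish,
which is exactly why both metrics are carried. Zero-denominator fold
changes are flagged undefined, never returned as infinity. Report
rounding follows the field's convention (abundances and pp to 1 decimal,
fold changes to 2), with full precision retained internally.

`compare_groups()` computes features at a chosen level (exact,
containment, combination, load), averages technical replicates within a
biological sample when asked, then applies Welch's two-tailed t for two
groups or one-way ANOVA with Tukey HSD for three, classifying each
contrast by the volcano convention: red = p < 0.05 and fold change beyond
|1.5| (symmetrically: > 1.5 or < 2/3), blue = significant only, grey =
large-fold only, black = neither.

# Cohort statistics

The named procedures are implemented from their formulas and validated
against independent oracles in the tests (base R's `t.test`, `aov`,
`TukeyHSD`, `p.adjust`, and exhaustive enumeration): Welch's t with
Welch–Satterthwaite degrees of freedom; one-way ANOVA with Tukey HSD via
the studentized range distribution; Benjamini–Hochberg step-up;
the Benjamini–Krieger–Yekutieli two-stage adaptive step-up (stage 1 at
q′ = q/(1+q), null count m₀ = m − r₁, stage 2 at q′·m/m₀); and the
hypergeometric upper tail with a Haldane-corrected odds ratio. Degenerate
inputs (zero variance everywhere with equal means) map to p = 1 with a
warning instead of NaN, keeping pipelines total. The BKY target level
defaults to 0.05, the conventional significance level used throughout.

A note on testing FDR control: under a complete null the two-stage
procedure rejects with probability q/(1+q) ≈ 0.0476, so the empirical
false-discovery proportion over a few hundred simulations sits close
enough to the 0.05 bound that a literal ≤ 0.05 assertion would fail by
sampling noise alone roughly a third of the time. The property test
therefore checks binomial consistency with the bound over 1000
simulations.

# Consensomes and HCT footprints

A consensome ranks a regulator's candidate target genes by mean ChIP-Seq
peak strength across datasets (`build_consensome`; a gene missing from a
dataset contributes 0 by default, mean imputation is selectable). Ranks
are descending with average-rank ties; the reported percentile is
100 × (1 − (rank − 1)/m), so the top gene sits at percentile 100 and the
percentile is invariant under monotone transformations of the scores.
High-confidence transcriptional targets (HCTs) are the genes strictly
above the 95 line — exactly the top 5%. The strict inequality is a
deliberate boundary choice: with the top-gene-at-100 convention, a
non-strict cutoff would admit the (0.05 m + 1)-th gene. With all scores
tied the ranking is uninformative and `hct_set()` returns every gene with
a warning.

`footprint_enrichment()` tests each node's HCT set against a query gene
set with the hypergeometric upper tail over a configurable gene universe
(default: the union of all genes seen; enrichment backgrounds matter and
the right universe is analysis-specific), adjusts across nodes by
Benjamini–Hochberg, and sorts by q then odds ratio.
`node_class_enrichment()` asks whether a marked node class concentrates
among the top-ranked footprints; `top_k` has no privileged value and must
be supplied, and both q- and odds-ratio-based rankings are exposed since
published scatter plots do not fix one.

# Differential methylation and expression integration

CpG calls (Bismark coverage dialect, 1-based) are filtered at minimum
coverage 10, normalized between samples by median scaling (factor =
median of per-sample median coverages / sample median, counts rounded
half-up, per-base methylation percentage preserved within rounding), and
summarized over promoters (TSS ± 1000 bp, strand-aware — the TSS of a
minus-strand gene is its annotation end) and gene bodies. Regions are
half-open 0-based internally (BED dialect); 1-based annotations are
accepted with a flag. The promoter window is configurable because no
single definition is canonical.

Per region, `differential_regions()` fits a binomial logistic regression
of (methylated, unmethylated) counts on group and tests the group term by
likelihood ratio, with Fisher's exact test on pooled counts as the
fallback below two samples per group. This is a documented stand-in for
methylKit's default testing (which applies a SLIM-based correction);
q-values here are Benjamini–Hochberg. Calls require q < 0.05 and a
methylation difference beyond |5| percentage points. The sign convention
is first-named group minus second, so naming the cold condition first
makes hypomethylation-under-cold negative.

`integrate_expression()` joins promoter calls with a differential
expression table and flags the canonical inverse associations:
hypomethylated promoter with up-regulated gene, or hypermethylated with
down-regulated, at the conventional thresholds (DM q < 0.05,
|meth diff| > 5; expression p_adj < 0.05 and |log2FC| ≥ 0.263, i.e. a 20%
change). Same-direction pairs are excluded; duplicate gene ids are
reported and resolved to the first match.

# Synthetic data: what the generators emulate

Every stage has a seeded generator; all are pure functions of their
arguments and a seed, restore the caller's RNG state, and fan one global
seed out to per-stage child seeds.

**Proteoform cohorts.** `study_profile()` encodes designed truth
compositions for each tissue (brown adipose tissue, liver) × housing
temperature (thermoneutral 28 °C, room temperature 22 °C, severe cold
8 °C) condition of the emulated cold-stress cohort. The compositions are
built so their marginals carry the cohort's group-level characteristics —
bulk H3.2 acetylation rising from 35.6% (TN) to 45.2% (SC) in BAT with
acetyl loads 0.51 to 0.63; H4 acetylation 36.9 to 39.4%, load 0.46 at SC;
the dominant H4 states <K20me2>/<K20me3> near 36/22% in BAT vs 39.4/19%
in liver; and the tissue-distinctive H3.2 proteoforms (<K9me2K27me1> 6.0
vs 1.7, <K9me3K27me1> 3.3 vs 0.5, <K9me2K27me3K36me1> 1.6 vs 3.7). Where
the emulated study prints no value (liver bulk percentages at some
temperatures, the mono/di-acetyl split), realistic values were fixed once:
di-acetyl share set by the load constraint, remaining methylation-only
mass split over a fixed filler repertoire whose K9me2 weight grows with
cold so {K9me2} rises and {K9un} falls. Replicates are drawn by
logistic-normal jitter (multiplicative log-normal noise, σ = 0.08 ≈ 8%
CV, then renormalization to 100) over the design of 3–5 animals per
group. These are synthetic compositions and say nothing about animals;
they give the algebra a ground truth with realistic structure.

**Top-down runs.** MS1 peaks at theoretical m/z across a charge envelope
with intensity proportional to abundance; one ETD scan per composition
whose fragment intensities are proportional to isomer abundances
(site-determining ions) or composition totals (shared ions); Gaussian ppm
jitter clamped at 3σ. Instrument duty cycle, dynamic exclusion and
chromatography are not simulated; "top-N" precursor selection appears
only as scan coverage.

**Consensome worlds.** Uniform peak strengths for null nodes; planted
regulators have their prospective top-5% genes overlap the induced gene
set at a configured rate (default 0.5 over a 2000-gene universe, 60
nodes, 3 datasets — sizes chosen to keep the full calibration loop
seconds-fast while leaving the hypergeometric tails far from degeneracy).

**Methylome cohorts.** Per-promoter baseline methylation Beta-distributed
in 0.2–0.8, planted differential regions shifted by the effect size
(default 40 pp; `planted_base` pins baselines when larger effects must
not clip), negative-binomial coverage, binomial methylated counts, and a
coupled expression table: planted hypo-promoters carry +1 log2FC
up-shifts (hyper mirror-image). The emitted DEG statistics use the exact
negative-binomial likelihood-ratio test at the known simulation
dispersion — the generator emulates the *output* of an NB differential
pipeline, and since the simulation knows its own dispersion it does not
re-estimate it; real pipelines must, and their power is correspondingly
lower near the detection boundary.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run: 20 spectral round-trip
runs of 5–30 proteoforms; exhaustive hypergeometric enumeration for
universes up to 25; 200–1000 null simulations for FDR calibration; 5 null
consensome worlds of 60 nodes × 2000 genes; methylation cohorts of
200–1000 promoters × 12 CpGs × 8 samples. These sizes make every
distributional check stable while keeping a full run in minutes.

EM iterations cap at 200 with a 1e-12 relative convergence check;
fractions below 1e-6 are zeroed and renormalized. Tukey p-values use R's
studentized-range distribution. BH/BKY operate on sorted copies and
restore input order. Region assignment uses `findInterval` with bounded
backtracking rather than a cross join, keeping memory linear in calls +
regions.

# Known limitations

- Quantitation accuracy is bounded by chimeric ambiguity: two different
  proteoform mixtures can produce indistinguishable fragment unions when
  precursors co-isolate; the per-scan design avoids this only as far as
  acquisition separated precursors.
- The methylation test is a methylKit-inspired stand-in, not a
  re-implementation; genome-wide call counts from real cohorts depend on
  alignment stacks and annotation versions outside this package's scope.
- The consensome stage consumes peak-strength tables; retrieval from
  ChIP-Atlas-like resources and peak calling are out of scope.
- H3 variants beyond H3.2 and PTM chemistries beyond acetylation and
  lysine methylation (ubiquitination, phosphorylation occupancy) are not
  modeled.
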