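Package: histoform
Title: Top-Down Histone Proteoform Quantitation and Epigenomic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of intact histone proteoforms from top-down
    mass spectrometry, and integration with regulatory-genomics readouts. The
    package models histone H3.2 and H4 proteoforms (site-resolved acetylation
    and lysine methylation), parses and formats the angle-bracket/curly-bracket
    proteoform notation, generates theoretical ETD c/z fragment ladders,
    matches and localizes positional isomers at user-set MS1/MS2 tolerances,
    and converts matched signal into percent-abundance tables. On those tables
    it provides the proteoform algebra (exact vs containment marginals,
    modification load per molecule, percentage-point and fold-change metrics,
    k-PTM combination enumeration) and the cohort statistics used in
    comparative studies (Welch t, one-way ANOVA with Tukey HSD, Benjamini-
    Hochberg and Benjamini-Krieger-Yekutieli FDR, hypergeometric enrichment).
    Companion modules build ChIP-Seq consensomes with high-confidence
    transcriptional target (HCT) footprint enrichment, call differentially
    methylated promoters and gene bodies from bisulfite coverage files, and
    flag genes whose promoter methylation is inversely associated with
    expression. Seeded generators provide planted-truth synthetic data for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
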