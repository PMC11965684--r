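Package: lcrevol
Title: Low-Complexity Region Composition, Complexity and Evolution in
    Protein Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies low-complexity regions (LCRs) in protein ortholog
    families: per-residue simplicity (SIM) and repetitiveness (REP) scores
    computed in a 20-residue sliding window, amino-acid percent occurrence,
    homopolymeric amino-acid repeat (AAR) detection with per-residue totals,
    and proteome-baseline enrichment flags. Includes the evolutionary stage
    of the analysis: per-clade parameter means, Pearson correlation of clade
    means against clade stem ages with two-tailed significance, per-species
    variants, random-subsampling robustness checks, and cross-paralog /
    cross-parameter correlations. A synthetic ortholog-family simulator with
    clade-age-dependent repeat expansion makes the whole pipeline testable
    without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
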