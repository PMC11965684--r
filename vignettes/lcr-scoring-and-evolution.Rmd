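---
title: "Scoring low-complexity regions and tracing their evolution across clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring low-complexity regions and tracing their evolution across clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrevol)
```

## The problem

Low-complexity regions (LCRs) — protein segments with biased, low-diversity
amino-acid composition, including homopolymeric amino-acid repeats (AARs) —
are common in the variable regions of RNA-binding protein families such as
the CPEBs, where they mediate liquid-liquid phase separation and prion-like
aggregation. Because LCRs expand, contract and change composition much
faster than folded domains, they are natural candidates for driving the
functional divergence of paralogs. `lcrevol` provides the quantitative
machinery for this kind of study: per-residue simplicity and repetitiveness
scores, composition and homorepeat profiling, and a clade-level correlation
stage that asks whether a parameter trends with clade stem age along a
lineage.

## The SIM and REP scores

Both scores are computed in a sliding window of 20 residues centred on each
residue (9 upstream, 10 downstream), clipped at the termini: the effective
window grows from 11 residues at position 1 to 20 at position 10, and
shrinks back to 10 at the final residue. Sequences no longer than the
nominal window are scored over the whole sequence at every position — the
only reading under which a 20-residue homopolymer attains the documented
per-protein mean REP of 20 (symmetric clipping alone would give its edge
windows REP values of 11–19).

**SIM (simplicity).** With $a$ the vector of 20 per-amino-acid counts in
the window and $b$ the number of amino acids present at least once,

$$\mathrm{SIM} = \frac{\mathrm{CV}(a)}{1 + \log b}.$$

CV is the *population* coefficient of variation (divide-by-$n$ standard
deviation over the mean of the 20 counts). Two numerical conventions are
deliberate:

* the quotient form is the only arrangement consistent with both documented
  endpoints — 0 for a window holding all 20 amino acids once, and
  $\sqrt{19} = 4.3589$ (printed truncated as 4.35) for a pure homopolymer;
  a product $\mathrm{CV}\cdot(1+\log b)$ would exceed 4.35 for a two-block
  window;
* the population SD is required for the 4.35 endpoint; the sample SD would
  give 4.47. The log base defaults to natural log and is exposed as an
  argument; the endpoints are base-independent because $\log 1 = 0$.

SIM is invariant to any permutation of the residues inside a window — it
measures composition bias only.

**REP (repetitiveness).** With $a$ the total length of maximal runs of
$\ge 2$ identical residues in the window, $b$ the number of such runs and
$c$ the number of distinct amino acids forming them,

$$\mathrm{REP} = \frac{a}{b \cdot c},$$

defined as 0 when no run exists (avoiding 0/0). REP ranges from 0 to 20,
with 20 attained only by a pure 20-residue homopolymer under this grouping
(the alternative grouping $(a/b)\cdot c$ would also award 20 to a window of
ten doublets). Given a fixed composition REP ranks blocked arrangements
above interleaved ones: for 10 A + 10 Q, `AQAQ…` scores 0,
`AAAAAQQQQQAAAAAQQQQQ` scores 2.5, and `A₁₀Q₁₀` scores 5 — order
sensitivity is exactly what distinguishes REP from SIM.

Ambiguity codes (B, J, O, U, X, Z) are accepted on input with a warning;
they occupy window positions but join no count and break runs. Positions
whose entire window is ambiguous yield `NA` SIM. Reported endpoint values
are compared after two-decimal *truncation* (`trunc_decimals()`), matching
the convention in which $\sqrt{19}$ prints as 4.35; stored values keep full
precision.

## Composition, AARs and enrichment

`aa_percentages()` reports percent occurrence of each amino acid;
`find_aars()` reports maximal runs of $\ge 4$ identical residues (1-based
inclusive coordinates internally, BED-convention 0-based half-open in
`write_aar_bed()` exports); `aar_totals()` sums, per amino acid, the
lengths of its individual repeats. The enrichment stage compares a protein
against a proteome baseline at a $\pm 20\%$ relative-deviation threshold,
motivated by a worked calculation: an average 500-residue protein with 8%
alanine that acquires an alanine-rich first 100 residues (16% A) reaches 48
alanines, i.e. 9.6% — a 20% relative increase — so deviations beyond 20%
can flag compositionally biased regions of even modest length. The flag
uses *strict* inequality, so that canonical boundary case is `neutral`.

The baseline is the **unweighted mean of per-protein percentages** ("mean
occurrence across all proteins"), not the pooled residue frequency; the
pooled variant is available via `proteome_baseline(..., pooled = TRUE)` for
sensitivity analysis — the two differ whenever protein lengths differ.

## The evolutionary stage

For each protein, `parameter_vectors()` assembles 42 built-in parameters
(20 percents, 20 AAR totals, mean SIM, mean REP) plus any ingested external
per-protein scores (LLPS propensity, prion-likeness, …; per-residue tracks
are averaged). The classic 24-parameter set of interest is the 20 percents
plus mean SIM, REP, an LLPS score and a prion score. `clade_summaries()`
takes unweighted means across the orthologs of each clade regardless of
clade size (single-sequence clades contribute their own values — how
unequal clade sizes should be weighted is genuinely open; unweighted means
keep the clade, not the species, as the unit of analysis).
`correlate_with_stem_age()` computes Pearson's $r$ against clade stem ages
with the two-tailed $p$ from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$
degrees of freedom, significance at $p \le 0.05$. Conventions worth
stating:

* **No multiple-testing correction** is applied across parameters — each
  test is marginal, which is a caveat, not an oversight: with 24 parameters
  roughly one nominally significant correlation is expected under the null.
* Negative $r$ means the parameter increases toward younger clades.
* Stem-age ties (Glires and Primates, both 87 Myr) need no special casing.
* Zero-variance inputs or fewer than 3 points yield an explicit undefined
  result (`NA` r/p), never an error mid-table.
* `normalize_to_reference()` (divide by the oldest clade's mean) is for
  reporting only; correlations always use unnormalized means — a
  per-parameter rescale cannot change $r$, and the tests assert this.

`per_species_correlation()` repeats the analysis with each ortholog
carrying its clade's stem age, quantifying robustness to intraclade
variability. `subsample_robustness()` re-runs the clade-mean analysis on
`k = 5` randomly chosen species per clade, `reps = 10` times, and tallies
both significance preservation and sign consistency (the two tallies are
reported separately because a repetition can keep significance while
flipping sign). One root seed deterministically derives per-repetition
seeds; `k` at least the largest clade size reproduces the full analysis
exactly.

Two registry fixtures ship for the vertebrate design — the primary one
(Chondrichthyes 462, Actinopterygii 429, Amphibia 352, Sauropsida 319,
Marsupialia 160, Atlantogenata 99, Laurasiatheria 94, Glires 87, Primates
87 Myr; TimeTree medians) and an alternative stem-age set
(`"vertebrate_alt"`) reflecting the spread of published dates for Amphibia,
Sauropsida, Marsupialia and Atlantogenata — plus a 21-clade ray-finned-fish
registry (Cladistia 396 → Poeciliinae 18.9 Myr) for intraclade contrasts.

## What the synthetic generator emulates

`simulate_family()` produces ortholog families with the statistical
structure the evolutionary stage assumes: several clades of known stem age,
each contributing orthologs built as `"M" + NTR + CTR`, where the CTR is a
conserved block shared up to per-site substitution noise and the NTR is
background sequence carrying planted homorepeat runs whose expected length
is linear in the clade's age offset (oldest stem age minus its stem age):
$\ell = \max(0, \mathrm{round}(\mathrm{base} + s \cdot \mathrm{offset} +
\varepsilon))$, $\varepsilon \sim N(0, \sigma)$. Positive slopes therefore
mean "grows toward younger clades" and yield negative stem-age
correlations. Planted runs are separated by at least one non-matching
residue and flanked by non-matching residues, so they stay maximal and
countable; runs are placed at random offsets via random gap sizes.

Defaults, chosen once as the simulated study conditions: the nine-clade
vertebrate registry; 10 species per clade (within the range of the smaller
real clades while keeping clade means stable); NTR 200 and CTR 300
residues (a compact protein with a conserved C-terminal block of realistic
domain size); CTR substitution rate 0.05/site (visible ortholog divergence
without eroding conservation); uniform background composition (the neutral
choice — a human-proteome-like preset `aa_frequencies("human")` is
available); planted polyproline effect base 4 residues, slope 0.04
residues/Myr of offset (4 → ~19 residues across 375 Myr, the scale of real
polyP elongation), jitter SD 1.5 residues. `null_family()` zeroes all
slopes for type-I experiments.

What the generator does **not** emulate: tree-structured descent (clades
are independent given their ages — no phylogenetic autocorrelation),
indels other than repeat-length jitter, composition heterogeneity along the
NTR, and real predictor scores. Passing recovery and type-I tests
therefore shows the *statistical machinery* is calibrated, not that real
families satisfy its assumptions; in particular plain Pearson correlation
on clade means, not phylogenetically independent contrasts, is what the
package implements by design.

## Validation problem sizes

The test suite validates (sizes are the package's own choices):

* brute-force per-window oracle equality of the SIM/REP profiles on 1,000
  random sequences (lengths 2–40, with and without ambiguity codes), plus
  score-bound fuzzing on 300 longer sequences;
* recovery: under the default generator conditions the planted polyP trend
  is detected (negative $r$, $p \le 0.05$) in $\ge 95\%$ of 200
  simulations;
* calibration: across 1,000 null families (5 species/clade, NTR 80, CTR
  40) the fraction of significant stem-age correlations lies in
  [0.02, 0.09], and 1,000 random 9-point series pairs are significant
  $\approx 5\%$ of the time;
* slope recovery: a linear fit of clade-mean polyP totals on age offset
  recovers the planted slope within 2 standard errors at 20 species/clade.

## Known limitations

* The QC rule replaces alignment-based inspection with a
  clade/paralog-median length-deficit heuristic (default 50 residues);
  records failing it are reported with reasons rather than silently
  dropped, but no alignment is performed.
* External predictor scores are ingested, never recomputed.
* Entropy-based (SEG-style) complexity, multi-residue-motif tandem repeats
  and cryptic simplicity are out of scope; "tandem repeats of at least two
  units" is read as runs of identical residues.
* Clade means ignore clade size; with 1–3 sequences per clade (as in the
  deep fish subclades) a "mean" is a single noisy observation.
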