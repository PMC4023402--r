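---
title: "Estimating acetylation stoichiometry from partial chemical acetylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating acetylation stoichiometry from partial chemical acetylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acstoich)
library(dplyr)
```

## The measurement problem

Occupancy (stoichiometry) is the fraction of a protein's copies acetylated
at a given lysine. Classical occupancy estimation compares a modified
peptide to its unmodified counterpart (the corresponding peptide, CP), but
that comparison only resolves occupancies high enough to visibly deplete
the CP — roughly the percent range. Most cellular acetylation sits far
below that. This package implements an inverse strategy: *partially*
acetylate the lysate chemically with acetyl-phosphate (AcP) in one SILAC
channel, mock-treat the other, and read each site's fold increase
`R = light/heavy`. The lower a site's pre-existing occupancy, the more
room chemistry has to add signal, so `R` is inversely related to occupancy.

## The bound and its assumptions

If AcP added at most `c_max` percent occupancy at every lysine, a site
observed at fold increase `R >= 1` satisfies

```
s0 < c_max / R
```

Two remarks on this estimator:

* **Why `c_max / R` and not the exact algebra.** Writing treated occupancy
  as `s1 = s0 + c` with chemical contribution `c <= c_max` and
  `R = s1/s0` gives exactly `s0 = c/(R - 1)`. The reported bound divides
  by `R` instead of `R - 1`, which is the convention of the anchor
  measurements this method was validated against and is what the headline
  rules (10-fold → < 0.1%, 20-fold → < 0.05%) encode. For `R >= 2` the
  difference only makes the bound *less* tight on one side
  (`c_max/R < c_max/(R-1)`), while the estimates are explicitly "less
  than" values; the package therefore keeps `c_max / R`.
* **The ceiling.** `c_max` defaults to 1% — deliberately far above the
  measured chemical degrees (median 0.07%, range 0.01–0.11% across eight
  AQUA-calibrated sites), so per-lysine reactivity variation is absorbed
  by the ceiling. It is configurable everywhere it appears.

Sites with `R < 2` move too little relative to measurement variability for
a meaningful bound; they are classed *AcP-insensitive* and reported only
as `> 1%`. Sites in `[1, 2)` fall in this class too — the scheme is
deliberately two-class. Ratios below 1 are rejected as a domain error:
decreased acetylation after treatment indicates a problem upstream, not a
stoichiometry.

## Sites without a SILAC ratio

When a site's untreated (heavy) peptide falls below detection no ratio
exists, but its absence is itself informative. The package estimates an
empirical detection limit — rank all observed heavy-channel peptide
intensities and take the median of the bottom 10% (set size
`max(1, floor(0.1 n))`; the floor is a deterministic, conservative choice
for small `n`) — and reports `light / limit` as a *minimum* fold increase,
hence `c_max / min_ratio` as the bound. Minimum ratios below 1 are kept,
flagged `"min_ratio<1"`, rather than dropped: they would usually indicate
generator or input errors, and silently removing them would hide that.

## AQUA absolute stoichiometry

For absolute calibration, acetylated and unmodified peptide intensities are
each compared to a spiked heavy-labeled standard of known amount:
`amount = (light/standard) * spike`, and occupancy is
`100 * ac/(ac + unmod)` percent. Initial occupancy divides the AcP-treated
occupancy by the fold increase (`s0 = s_acp / R`) and the chemical degree
is the difference (`c = s_acp - s0`). Report columns mirror the print
precision of the reference table: stoichiometries at 4 decimals, degrees at
2, rounded half-up (`round_half_up()`), with the degree differenced against
the *printed* initial stoichiometry so that the printed triple
(`s_acp`, `s0`, `c`) is internally consistent at its own precision. All
internal computation is at full precision. Two of the eight shipped
reference rows were published from unrounded instrument values and do not
round-trip from their printed inputs; `aqua_reference_sites()` marks the
six self-consistent rows, and tests assert recomputation only on those.

## Abundance-corrected intensity (I/iBAQ-A)

An independent, treatment-free occupancy proxy: the acetyl peptide's
untreated-channel intensity divided by the protein's iBAQ abundance
(protein intensity over its count of observable tryptic peptides). The
digest rule is the standard iBAQ convention — fully tryptic, cleavage after
K/R blocked before P, zero missed cleavages, observable length 7–30
residues. Missing protein abundance yields an absent score, never zero.

## Dynamics layer

* Site ratios are corrected for protein abundance change by division in
  linear space; log2 is applied only for reporting. Sites lacking a protein
  ratio are flagged and excluded from corrected analyses, not dropped.
* Compartment summaries use proteins localized *exclusively* to one of
  mitochondrion, cytoplasm or nucleus; medians are reported in both log2
  and linear form (medians commute with monotone transforms, so
  `linear = 2^log2` holds exactly).
* "Wilcoxon test" means the two-sample rank-sum test: compartments are
  independent site sets. Exact enumeration when the smaller group has at
  most 8 observations and no ties; otherwise the normal approximation with
  midranks, tie-corrected variance and continuity correction (the same
  contract as `stats::wilcox.test`, which backs the implementation; the
  test suite checks it against a from-scratch enumeration oracle).
* Term enrichment is a one-sided hypergeometric tail — enrichment is a
  one-tailed question. No correction convention is assumed by the method
  itself; outputs carry raw p-values and Benjamini–Hochberg adjusted
  values side by side, with the correction recorded in the result's
  metadata as this package's choice.
* TMT dose-response: records pass the parent-ion purity filter at
  `purity >= 0.90` (inclusive — a "minimum of 90%" reading); relative
  abundance is a ratio of channel means with a two-tailed pooled-variance
  t-test. Zero-variance groups return a flagged degenerate result
  (p = 0 if means differ, 1 if identical) instead of a fabricated
  statistic.
* Acetyl-CoA pool arithmetic: the wild-type minus pda1-null total measures
  the mitochondrial pool; the same subtraction in a cit1-null background,
  divided by it, is the mitochondrial fold change. A pool fraction `p` in
  volume fraction `v` implies an in/out concentration ratio
  `(p/v)/((1-p)/(1-v))` — one third of the pool in 1.5–2% of the volume is
  a 20–30-fold concentration difference.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the processed
tables, not the mass spectrometry itself:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 300 | ~600 sites; large enough for stable distributional tests, small enough for seconds-scale suites |
| abundance | log-normal, meanlog `log(1e9)`, sdlog 1.5 | iBAQ-like span of several orders of magnitude |
| compartments | mito .20 / cyto .40 / nuc .25 / other .15 | plausible proteome shares with all compartments well populated |
| sites/protein | Poisson(2) | a few sites per acetylated protein |
| low occupancy | log-uniform 1e-4–1e-1 % | the low-stoichiometry regime the method targets |
| nuclear high fraction | 0.20 of nuclear sites, log-uniform 1–100 % | a high-occupancy nuclear subpopulation; overall ~95% of sites below 1% |
| reactivity | log-normal, median 0.07 %, sdlog 0.7, truncated at 1 % | median matches the measured chemical degrees; the distribution shape is a modeling choice — only eight per-lysine values were ever measured |
| mito basal multiplier | 3× | mitochondrial sites start at a higher basal occupancy, hence lower `R` |
| `noise_cv` | 0.2 | replicate-level multiplicative intensity noise |
| `detection_threshold` | 3e4 | censors roughly the fraction of heavy channels seen in practice (about half the sites lack ratios) |

Treatment chemistry acts on the unmodified fraction:
`s1 = s0 + c (1 - s0/100)` — chemical acetylation can only convert
unmodified lysines, and this reduces to the additive picture when `s0` is
small. It also explains why high-occupancy sites are AcP-insensitive: at
`s0 = 50%` and `c = 0.5%`, `R ≈ 1.005`.

What the generator does **not** model: ionization efficiency differences
beyond a site-level log-normal factor, correlated noise between channels,
peptide misidentification, protein inference ambiguity, retention-time or
chromatography effects. Passing the synthetic acceptance properties
therefore demonstrates the estimators' correctness under the stated model,
not robustness to every artifact of real data.

## Numerical and degenerate-input choices

* Report rounding is half-up on the decimal value; R's default banker's
  rounding would print 0.0755 as 0.07.
* `stoichiometry_fractions()` counts flagged `">1%"` sites in every
  denominator and no numerator: their occupancy is unknown above 1%, so
  claiming them below any threshold — or above a specific one — would be
  unjustified. Whether the ratio-bearing population is delimited at
  `R > 1` or `R >= 2` is left to the caller's filtering; the package does
  not assert either convention.
* Invalid rows in input tables are dropped with exactly one row-indexed
  diagnostic each (kept in the `"problems"` attribute); required-column
  failures are table-level format errors naming the column.
* Empty groups, empty ratio lists, inconsistent contingency counts and
  non-positive intensities are domain errors, not silent `NA`s.

## Problem sizes and determinism

The test suite and the synthetic acceptance properties run on the default
generator (300 proteins, ~600 sites) and fixed seeds; the whole suite
completes in seconds on one core. All randomness in a pipeline run flows
from the single seed recorded in the JSON manifest, and identical seeds
produce byte-identical outputs.

## Known limitations

* Bounds are upper bounds, not estimates; two sites with equal bounds may
  differ widely in true occupancy.
* Inaccessible or unreactive lysines violate the ceiling assumption in the
  other direction and can masquerade as high-occupancy (insensitive)
  sites.
* Isotope-impurity correction, protein grouping and absolute occupancy
  without AQUA standards are out of scope.
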