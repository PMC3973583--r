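---
title: "Detecting toxin-resistance mechanisms from expression data: methods and design"
author: "amaresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting toxin-resistance mechanisms from expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amaresist)
```

# Overview

`amaresist` implements the computational chain used to look for
gene-regulatory mechanisms behind alpha-amanitin resistance in
*Drosophila melanogaster* larvae: dose-response LC50 estimation, rank-product
differential expression between replicated groups, a sliding-bin binomial
coincidence scan for genomic clusters of differentially expressed genes
(DEGs), hypergeometric term and protein-domain enrichment, and a
randomization test for qPCR validation ratios. Every stage is driven by a
synthetic-data generator that emulates the study design, so the whole chain
is testable against known ground truth without any external download.

This vignette documents the models, the tunable parameters, the numerical
choices, and the design decisions that were genuinely open — together with
what the synthetic tests do and do not show about real data.

# The synthetic study design

The generator emulates a three-group larval design: a sensitive stock on
clean food (group 1, 5 biological replicates), a resistant stock on clean
food (group 2, 5 replicates), and the resistant stock raised on toxin
(group 3, 6 replicates). Defaults, chosen once:

* **11,890 genes** on the five major chromosome arms (X, 2L, 2R, 3L, 3R)
  with dm3-like lengths of 22.4/23.0/21.1/24.5/27.9 Mb. Each gene is a 1-kb
  span centred on a uniform-random midpoint; arm choice is
  length-proportional.
* **Baseline intensities** are log-normal (meanlog 6, sdlog 1 on the
  natural log): a heavy-tailed positive distribution matching the shape of
  summarized microarray intensities. The true intensity distribution of the
  original arrays is unknown; these are stand-ins, not estimates.
* **300 planted DE genes** with linear fold effects drawn log-uniformly
  from 2 to 300 (the range spanned by the strongest reported single-gene
  changes), half up- and half down-regulated; effects act in group 2.
  Signed folds are recorded as the ratio when >= 1 and as minus its
  reciprocal otherwise.
* **Multiplicative noise** with coefficient of variation 0.2 per sample
  (log-normal with unit mean) — a typical between-replicate CV for
  summarized arrays of pooled larvae.
* **One planted cluster**: 40 of the DE genes receive midpoints inside one
  500-kb window on arm 3L.
* **Annotations**: 150 GO-style terms with log-uniform sizes between 10 and
  400 genes, and 120 protein domains assigned as Poisson(1.5) instances per
  gene with Zipf-like domain frequencies, so a few domains are common and
  most are rare — the shape of real domain catalogs.
* **Dose-response truth**: survival = 1 / (1 + (C/LC50)^2), a smooth
  monotone curve equal to 1 at C = 0 and 0.5 at the LC50. Any monotone
  curve through (LC50, 0.5) would do; this one is simple and
  differentiable.
* **qPCR truth**: Ct = 34 - log_E(expression) + Gaussian noise (default SD
  0.1 cycles per measurement), with efficiency E = 2 (perfect doubling) and
  two reference genes whose expected expression is equal in both groups.

What the generator does **not** emulate: probe-level effects, batch
effects, missing values, correlated noise across genes, annotation bias,
or the real genome's gene-density structure (genes are uniform on arms).
Passing tests therefore demonstrate that the implementations are correct
and calibrated under the stated model, not that the original biological
conclusions would be recovered from the deposited raw data.

# Rank-product differential expression

For groups A and B with a and b replicates, each of the K = a x b pairwise
replicate comparisons ranks all G genes by pairwise fold change (rank 1 =
most changed in the direction under test; ties share the average rank). The
rank product is the geometric mean of a gene's K ranks, computed separately
for up- and down-regulation. Small rank products indicate consistent
regulation.

## The permutation null

Significance comes from a pooled permutation null:
`p = (1 + #{null RP <= observed RP}) / (1 + G * n_perm)`.

Two null schemes are implemented, and the choice matters:

* **Label permutation (default).** Each permutation reassigns the pooled
  a + b samples to the two groups at random and recomputes the rank
  product. Because the K comparisons share replicates, a gene's ranks are
  *correlated* across comparisons; relabelling preserves exactly that
  dependence, so null p-values are uniform (measured KS statistic 0.007 on
  the directional p-values at 10,000 genes). Random relabellings that
  reproduce the observed partition (or its mirror) are rejected whenever
  other relabellings exist: the +1 pseudo-count already accounts for the
  observed statistic, and drawing it again would inject full copies of any
  real signal into the null. With 5 vs 5 replicates there are only
  choose(10,5) = 252 distinct relabellings, so without this rejection about
  80% of runs with 200 permutations would draw at least one such copy —
  measurably costing sensitivity for moderate folds.
* **Independent-rank permutation (`null = "ranks"`).** Each comparison's
  rank vector is replaced by an independent uniform permutation of 1..G.
  This is the textbook construction for the rank-product null and admits a
  closed form at the extreme (P(RP = 1) = G^-K), but it ignores the
  cross-comparison dependence: on a replicated 5 vs 5 design with CV 0.2 it
  is severely anti-conservative (measured: 30% of null genes below p =
  0.05). It is retained because its closed form makes it an exact test
  target, and for designs where each comparison uses disjoint sample pairs
  it is appropriate — but it is not used for inference here.

## Combining directions and multiplicity

The per-gene p-value is `min(1, 2 * min(p_up, p_down))`: two one-sided
tests with a Bonferroni factor of 2. Up- and down-rank products are
strongly negatively associated, so the combined p is uniform in the
rejection region and mildly conservative near 1 (ECDF deficit up to ~0.07
around p = 0.95) — harmless for FDR control, which only engages the left
tail. Benjamini-Hochberg correction is applied across all genes
(`stats::p.adjust`); the DEG set is `q < 0.05` (strict), and the reported
set additionally requires at least a 2-fold change in either direction.

Defaults: `n_perm = 1000` for analyses (the tests and the acceptance runs
use 200, which already gives a p-value floor of ~4e-7 at 11,890 genes —
far below the BH thresholds in play — at a fifth of the cost). Fold changes
are computed on the linear intensity scale as ratios of group means.

# The binomial coincidence scan

Overlapping bins of width 500 kb are tiled every 250 kb from coordinate 0
along each arm independently (terminal bins truncated at the arm end, every
coordinate covered). The scan takes the top fraction `q_frac = 0.01` of
most differentially expressed genes — ranked by per-gene p-value with ties
broken by larger absolute fold, then gene id — and asks, per bin, whether
it holds more top genes than a Binomial(n_bin, 0.01) null allows: the bin
score is `log10(1 / P(X >= k))`, and bins scoring strictly above 2 (a
1-in-100 event under the null) are merged into cluster calls when they
overlap or touch.

Numerical and design choices:

* Genes are assigned to bins by midpoint, so per-bin counts are
  independent of gene length and no gene is double-counted within a bin.
* The null probability is fixed at the selection fraction (0.01), not the
  realized fraction floor(G q)/G; the difference is below 1e-4.
* Truncated terminal bins are scored like any other bin — the binomial
  model conditions on the bin's own n, so smaller bins simply have less
  power.
* Empty bins and bins without top genes score exactly 0 since P(X >= 0)=1.
* Calibration is verified by placing genes uniformly and flagging 1% at
  random: the pooled fraction of bins above the cutoff stays below 0.01
  plus Monte-Carlo error (measured ~0.004 across 50 placements; the test
  allows the nominal 0.01 plus three standard errors). The fraction sits
  below the nominal rate because bin scores are discrete: the attainable
  tail probability just above a score of 2 is typically well below 0.01.

# Enrichment: two counting modes

Both modes share the same machinery — exact hypergeometric upper tail
(the E_score), enrichment factor EF = kN/(nM), BH correction across all
rows of a run — but count different things, and conflating them changes
every number:

* **Gene mode** (GO-style term enrichment): N = background genes, M =
  background genes carrying the term, n = DEG genes in the background, k =
  DEG genes carrying the term. The default background is annotation-aware
  (genes with at least one annotation), the convention of the classic
  term-enrichment tools; a whole-genome background is available via
  `background = "all"`.
* **Domain-instance mode**: counts domain *instances*, so a gene with two
  copies of a domain contributes two. N = all instances genome-wide, M =
  instances of the domain, n = instances on DEG genes, k = instances of
  the domain on DEG genes.

No GO-graph propagation is performed: annotations are taken as given.
The BH family is all terms (or domains) tested within one run.

A note on consistency of the published values: the domain table's top row
(k = 48, n = 2609, M = 91, N = 11890) prints a corrected p of 4.72e-11,
but the exact inclusive tail of those counts is 1.121e-10 — larger than
the printed *corrected* value, which a BH correction can only increase.
No standard variant (exclusive tail, binomial or Poisson approximation)
reproduces the printed number either, so that printed p-value cannot be
reconciled with its own printed counts; the enrichment factor (2.404) and
the count geometry are reproduced exactly. The package keeps the exact
inclusive tail.

# Dose-response LC50

Vial-level survival fractions are averaged per concentration (s.e.m. = SD
of unit fractions / sqrt(units); units are vials by default, or replicate
experiments when given). The LC50 comes from the spreadsheet-style
logarithmic trendline: ordinary least squares of mean survival fraction on
ln(C), excluding C = 0, solved at 50% survival: LC50 = exp((0.5 - b)/a).
This mirrors the original scatter-plot procedure rather than substituting
a probit/logit model. The fit errors out when the slope is non-negative
("non-monotone dose response") or when the solved LC50 leaves
[min C / 10, max C x 10]; zero-concentration vials feed an 80%-survival
quality gate that warns and flags rather than aborts. The estimator is
exactly scale-equivariant in concentration units, and on data whose truth
is exactly log-linear it is consistent; on the logistic truth curve the
log-linear fit is a local approximation, recovered within a few percent at
the study's design (11 log-spaced concentrations spanning LC50/8 to
LC50 x 8, 100 larvae per concentration).

# qPCR ratios and the randomization test

Technical replicates are averaged into their biological replicate; the
expression ratio of a target t between groups is
`E_t^dCt_t / geomean_r(E_r^dCt_r)` over the reference genes r, with
dCt = mean Ct(A) - mean Ct(B). Efficiencies default to 2 (perfect
doubling) since none were reported for the original assay. Normalization
makes the ratio invariant to any Ct offset shared by all genes of a run.

The randomization test reallocates biological replicates between the two
group labels (jointly across target and references), B = 2000 times by
default, and compares |log ratio|:
`p = (1 + #{null >= observed}) / (B + 1)`, two-sided; ties count toward
the null, and group-label swaps leave the p-value unchanged while exactly
inverting the ratio. With 5 + 5 replicates only 252 distinct reallocations
exist, so the attainable p floor is about 2/252 ~ 0.008 — reported
p-values near 0.01 for overwhelming effects are a property of the design,
not a weakness of the effect.

# Problem sizes used in tests and checks

Unit tests run on reduced designs (hundreds of genes, 100-200
permutations) chosen so the whole suite completes in well under a minute
of compute per file while keeping every statistical check at its stated
tolerance; the end-to-end recovery checks and the acceptance script run
the full 11,890-gene design with 200 permutations and 50 null placements
of the genome scan. All randomness flows from a single seed through
`derive_seed(seed, stage)`, so every stage is individually reproducible.

# Known limitations

* The generator's noise model is i.i.d. multiplicative per sample; real
  arrays show correlated, intensity-dependent noise. Calibration results
  transfer only to the extent that ranks are insensitive to this.
* The label-permutation null has limited resolution for very small
  designs (few distinct relabellings); with 5 vs 5 replicates and 200
  permutations the p floor is already far below any BH threshold used
  here, but 2 vs 2 designs would be coarse.
* The log-trendline LC50 is a linear approximation to a sigmoid dose
  response; it is faithful to the original procedure but will be biased
  when the tested concentrations are asymmetric around the true LC50.
* The original probe-level normalization (PLIER summarization of CEL
  files) is out of scope; the pipeline consumes a normalized gene-level
  matrix.
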