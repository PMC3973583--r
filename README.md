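# amaresist

Detecting candidate toxin-resistance mechanisms from gene expression data
in *Drosophila melanogaster*.

Alpha-amanitin, the main toxin of death-cap mushrooms, inhibits RNA
polymerase II, yet some wild-derived fly stocks survive on food containing
it. Given a normalized gene-by-sample expression matrix from resistant and
sensitive larvae, this package asks where that resistance comes from at the
transcriptome level: which genes are differentially expressed, whether the
differentially expressed genes (DEGs) cluster in particular genomic
regions (pointing at shared regulatory control), and which functional
terms and protein domains they are enriched for — plus the organismal
anchors of such a study, dose-response LC50 estimation and qPCR
validation. It is aimed at analysts re-running or stress-testing this kind
of resistance study; every stage is driven by a synthetic-data generator
with known ground truth, so the full chain is testable offline.

## The statistics at the core

* **Rank-product DEG calling.** For groups with a and b replicates, each of
  the K = a×b pairwise replicate comparisons ranks genes by fold change;
  the rank product is the geometric mean RP_g = (∏ r_gk)^(1/K), computed
  per direction. Significance comes from a pooled permutation null
  (group-label permutation by default), p = min(1, 2·min(p_up, p_down)),
  Benjamini–Hochberg correction, DEGs at q < 0.05, reported genes
  additionally at |fold| ≥ 2.
* **Binomial coincidence scan.** Overlapping 500-kb bins every 250 kb on
  each chromosome arm; with the top 1% most differentially expressed genes
  flagged, a bin holding k flagged of n resident genes scores
  log10(1 / P(Binomial(n, 0.01) ≥ k)); bins above 2 (a 1-in-100 null
  event) merge into cluster calls.
* **Enrichment.** Exact hypergeometric upper tail (E_score) and enrichment
  factor EF = kN/(nM), counting genes (GO-style terms) or domain
  instances (protein domains), BH-corrected.
* **LC50.** Ordinary least squares of mean survival fraction on ln(C)
  (the spreadsheet "logarithmic trendline"), solved at 50% survival;
  resistance ratio = LC50_resistant / LC50_sensitive.
* **qPCR validation.** Reference-gene-normalized expression ratios
  E_t^ΔCt_t / geomean_r(E_r^ΔCt_r) with a B = 2000 randomization test over
  biological replicates.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_genome_scan.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_dose_response.R
Rscript analysis/06_qpcr_validation.R
```

Printed output of the central stages:

```
DEGs (q < 0.05): 296; reported (also |fold| >= 2): 296 of 11890 genes (2.5%)
planted |fold|>=4 sensitivity: 100.0%; false calls among DEGs: 0

scored 477 bins; 1 cluster(s) called:
  arm   start     end peak_score n_bins
1  3L 8250000 9250000   10.90925      3

Log-trendline LC50 fit
  survival = -0.2794 * ln(C) + 0.6918
  LC50 = 1.987  (QC pass)
true LC50 was 2.0; relative error 0.6%
resistance ratio of the published stocks: 77.1

qPCR validation (group2 vs group1, normalized to Sucb/alphaTub84B):
     gene     ratio     p_value    B
   Cyp6a2 10.169543 0.006996502 2000
 Cyp316a1  8.124451 0.008995502 2000
```

Reading this: the simulation planted 300 DE genes (2- to 300-fold) in an
11,890-gene transcriptome; the rank-product stage recalls all strong ones
with no false calls. The scan finds exactly one cluster, and it overlaps
the planted 500-kb window on arm 3L (peak score 10.9, i.e. a null
probability of 10^-10.9 for that bin's gene count). The LC50 fit recovers
the planted truth of 2 μg/g within 0.6%, and the qPCR stage recovers the
planted 10- and 8-fold ratios with randomization p ≈ 0.007–0.009 — near
the resolution floor of 5+5 replicates (≈ 2/252).

The same chain can be pointed at real data by replacing the files under
`results/synthetic/` with your own expression, group-map, catalog and
annotation TSVs (formats documented in `?read_expression`,
`?read_catalog`, `?read_annotations`).

## Package layout

* `R/` — simulation, rank-product, genome scan, enrichment, dose-response,
  qPCR, TSV I/O, and the `run_pipeline()` driver.
* `analysis/` — the numbered workflow scripts shown above.
* `vignettes/amanitin-resistance-workflow.Rmd` — models, parameter
  choices, calibration evidence, and known limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles for every tail probability and the FDR correction.
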