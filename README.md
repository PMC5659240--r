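# tutag — differential enrichment analysis for TU-tagging experiments

TU-tagging marks RNA synthesized in a genetically defined cell population:
a Cre-restricted UPRT transgene converts injected 4-thiouracil into
4-thiouridine, and thiol-tagged transcripts are biotinylated and pulled
down on streptavidin. Deciding which genes a cell population actually
expresses then becomes a count-based enrichment problem between purified
RNA sample types — for example, a layer 2/3-weighted cortical driver
("Sepw1") against a layer 4 driver ("Nr5a1"), or against the purification
background from animals carrying no UPRT at all ("WT").

`tutag` is an R package for exactly this analysis, aimed at people
running (or modeling) cell-type-specific metabolic labeling experiments:

* **Differential enrichment** between two purified sample types:
  counts-per-million low-count filter (a gene is dropped when ≥ 3 samples
  sit below 1 CPM), median-of-ratios size factors, per-gene
  method-of-moments NB dispersions with a fitted trend
  φ(μ) = a₀ + a₁/μ and conservative ("maximum") sharing, an exact NB
  test conditioning on each gene's total count, Benjamini–Hochberg
  adjustment, and enrichment calls at padj < 0.1 with fold enrichment
  > 1.
* **Resampling overlap test** of an enriched list against layer-marker
  gene sets: B = 1000 draws of equal size from the filtered universe,
  the distance-based two-sided p
  p = (#{x < m̂ − d} + #{x > m̂ + d})/B with d = |obs − m̂|, empirical
  95% percentile bands with explicit above/below-CI flags, plus a
  hypergeometric closed-form cross-check and a (count+1)/(B+1) corrected
  p.
* **Rank-based logistic model**: genes ranked by descending fold
  enrichment (rank 1 = strongest), marker-set membership regressed on
  rank by a from-scratch IRLS fit with Wald inference.
* **Leading-fold-change MDS**: pairwise sample distances as the RMS of
  the 500 largest absolute log2 ratios of normalized counts, embedded by
  classical MDS.
* **A synthetic TU-tagging count generator** with known ground truth,
  modeling the assay's two characteristic noise sources: background
  carryover (a fraction b of unlabeled total RNA in each purified
  sample) and labeling dynamics (the newly transcribed fraction
  r = 1 − exp(−ln2·T/t) of a transcript with half-life t over a T-hour
  window, so the purified-vs-background contrast spuriously enriches
  short-lived transcripts).

## Worked example

The `analysis/` scripts run the whole workflow as numbered steps
(simulate → differential enrichment → overlap → rank model/MDS), writing
tables under `results/`. Step 1 plants 100 markers per cortical layer in
a 5,000-gene universe and simulates 3 replicates each of the three sample
types; steps 2–4 printed the following on the run shipped with this
repository's scripts (seed 20170925):

```
Sepw1_vs_Nr5a1: 4998 genes after filtering, 75 enriched (padj < 0.1); dispersion trend a0=0.0197 a1=2.27
Sepw1_vs_WT: 4996 genes after filtering, 835 enriched (padj < 0.1); dispersion trend a0=0.0199 a1=3.36

Sepw1_vs_Nr5a1 (75 enriched):
  L2/3         overlap  72 expected   1.53  p=0 *above CI*
  L4           overlap   0 expected   1.52  p=0.058
  L5           overlap   0 expected   1.49  p=0.179
Sepw1_vs_WT (835 enriched):
  L2/3         overlap  56 expected  16.63  p=0 *above CI*
  L4           overlap  19 expected  16.79  p=0.518
  L5           overlap   5 expected  16.71  p=0.001 *below CI*
Venn vs layer 2/3 set: only purified-vs-purified 23 (87.0%), shared 52 (100.0%),
  only background 783 (0.5%)
Sepw1_vs_Nr5a1: slope -0.00671 per rank (Wald z = -9.9, p = 2.84e-23)
Sepw1_vs_WT:    slope -0.000761 per rank (Wald z = -8.1, p = 5.74e-16)
```

Read this the way the assay intends: the purified-vs-purified comparison
calls few genes but almost all of them are true layer 2/3 markers
(overlap 72 of 75 against a resampling expectation of 1.5, far above the
95% band); the purified-vs-background comparison calls ten times more
genes, its enriched list is dominated by non-layer-specific and
short-half-life transcripts (layer 2/3 precision collapses to ~7%, and
deep-layer sets fall *below* their bands), and the logistic slope —
the decay of marker probability with enrichment rank — is an order of
magnitude steeper for the purified-vs-purified contrast. The recovered
dispersion trend (a₀ ≈ 0.02, a₁ ≈ 2) matches the generating values.

The same run is available programmatically:

```r
library(tutag)
report <- run_pipeline(list(
  simulation = list(n_genes = 5000, seed = 20170925),
  comparisons = list(c("Sepw1", "Nr5a1"), c("Sepw1", "WT")),
  seed = 20170925
), out_dir = "results/run")
```

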