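---
title: "Methods: differential enrichment analysis for TU-tagging experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enrichment analysis for TU-tagging experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

TU-tagging restricts metabolic RNA labeling to a genetically defined cell
population: a Cre-driven UPRT transgene converts injected 4-thiouracil
into 4-thiouridine, so only transcripts synthesized in UPRT⁺ cells during
the labeling window carry the thiol mark and survive streptavidin
purification. Comparing purified RNA from a layer 2/3-weighted driver
against purified RNA from a layer 4 driver — or against the purification
background of animals with no UPRT at all — turns a cell-type question
into a count-based differential enrichment problem.

This package implements that analysis end to end: low-count filtering,
negative-binomial (NB) differential enrichment between purified sample
types, a resampling test for overlap between enriched lists and cortical
layer-marker gene sets, a rank-based logistic model of layer membership,
and sample-level multidimensional scaling. Because the real purification
experiment cannot be rerun at will, the package also ships a synthetic
count generator with known ground truth whose noise structure mimics the
two dominant artifacts of the assay: background carryover and
transcription-rate/half-life dynamics.

## The generative model behind the simulator

Each gene $g$ has a baseline abundance $\lambda_g$ (arbitrary expression
units), a probability vector of layer weights $w_{g,\ell}$ over the
layers (five patterned layers plus an unpatterned compartment), and a
half-life $t_g$ in hours. A sample type is characterized by a population
profile $\pi_\ell$ — the fraction of its captured transcription coming
from each layer. Under first-order decay, the fraction of a steady-state
transcript pool synthesized during a labeling window of $T$ hours is

$$r_g = 1 - e^{-\ln 2 \cdot T / t_g},$$

so short-lived transcripts are almost fully labeled while long-lived ones
are barely labeled. The expected purified abundance of gene $g$ in a
UPRT⁺ sample type is a two-component mixture

$$\mu_g = (1-b)\,\lambda_g \Big(\sum_\ell \pi_\ell\, w_{g,\ell}\Big) r_g
        \;+\; b\cdot \mathrm{bg}_g,
\qquad
\mathrm{bg}_g = \lambda_g \sum_\ell \pi^{\mathrm{tissue}}_\ell\, w_{g,\ell},$$

where $b$ is the background (carryover) fraction and $\mathrm{bg}_g$ is
the total-RNA abundance of the gene in bulk tissue, *not* weighted by
$r_g$ — carryover is unlabeled steady-state RNA. The no-UPRT control
captures background only, scaled by a capture efficiency
`wt_capture_scale` $< 1$. Counts are drawn NB with mean $s_j \mu_g$
($s_j$ a per-sample library factor drawn uniformly from
`library_size_range`) and dispersion $\phi = a_0 + a_1/(s_j\mu_g)$, the
standard dispersion–mean trend of bulk RNA-seq.

Two consequences of this mixture are worth spelling out, because the
analysis is designed around them:

* With $b = 0$ and equal half-lives, the expected purified-vs-background
  log-ratio of an unpatterned gene is the same for every gene. With
  heterogeneous half-lives it is strictly decreasing in $t_g$: the
  purified-vs-background comparison preferentially "enriches" short-lived
  transcripts regardless of cell type. This is the dynamics noise that
  makes the background comparison unreliable, and the test suite checks
  it exactly on expected values and stochastically on counts.
* Comparing two purified UPRT⁺ types cancels both the background term and
  the $r_g$ weighting for genes whose layer weights the two populations
  share, which is why the purified-vs-purified contrast isolates
  layer-specific expression far more cleanly.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `labeling_window_h` | 5 | time between 4TU injection and tissue collection |
| `n_replicates_per_type` | 3 | typical purification experiment scale; any ≥ 2 works |
| `background_fraction` | 0.2 | substantial but minority carryover, consistent with a no-UPRT purification yielding well-measurable RNA |
| `wt_capture_scale` | 0.1 | no-UPRT yield is an order of magnitude below UPRT⁺ yield |
| `effect_size` | 4 | fold elevation of a marker's home-layer weight; top-of-database layer markers are strongly, not marginally, enriched |
| `frac_markers_per_layer` | 0.02 | mirrors 400-gene marker sets per layer in a ~20,000-gene universe |
| `baseline_meanlog`, `baseline_sdlog` | log(5000), 1.2 | per-gene depth matching tens of millions of reads over an expressed-gene universe (mean counts ~10³) |
| `half_life_median_h`, `half_life_sdlog` | 5, 0.8 | mammalian mRNA half-lives center on a few hours and span roughly 1–20 h |
| `dispersion_a0`, `dispersion_a1` | 0.02, 2 | typical bulk biological CV of ~14% at high counts plus shot-noise-like inflation at low counts |
| `library_size_range` | (0.7, 1.4) | realistic library-size spread; exercises size-factor estimation |

The default population profiles put 55% of the "Sepw1" capture in layer
2/3 with 20% in layer 4 (a layer 2/3-weighted driver with lesser layer 4
activity), concentrate "Nr5a1" on layer 4 (72%), and spread the bulk
tissue profile uniformly. Deep-layer and unpatterned mass are equal
across the two purified profiles, so the expected purified-vs-purified
fold differs from 1 only for layer 2/3 and layer 4 markers — this gives
the simulation clean truth labels for sensitivity and FDR.

What the generator deliberately does **not** model: per-animal biological
variation within pooled samples (only per-sample NB dispersion), read- or
UMI-level structure, spatial structure within a layer, and a
non-expressed gene compartment (the universe represents genes already
restricted to expressed protein-coding annotation, so the CPM filter
passes nearly everything on synthetic data; the filter rule itself is
tested on constructed fixtures). Passing tests on this generator
therefore demonstrate correctness of the statistical machinery under the
assay's stated noise model, not robustness to every artifact of real
libraries.

## The differential enrichment stage

The stage reimplements the classic NB exact-test workflow for a
two-group comparison, rather than wrapping an existing package, because
its exact behavior is the quantity under study:

1. **Low-count filter.** A gene is removed when three or more of the
   comparison's samples have fewer than 1 count per million; CPM uses the
   comparison's samples with pre-filter library sizes.
2. **Median-of-ratios size factors.** $s_j = \mathrm{median}_g\,
   k_{gj}/(\prod_{j'} k_{gj'})^{1/m}$ over genes with nonzero counts in
   every sample (computed on the log scale).
3. **Dispersions.** Per-gene method-of-moments estimates from pooled
   within-condition variances of normalized counts,
   $\phi_g = (v_g - \bar\xi \mu_g)/\mu_g^2$ with $\bar\xi$ the mean
   reciprocal size factor; a parametric trend $\phi(\mu) = a_0 + a_1/\mu$
   fitted by iterated Gamma-family regression to genes with positive raw
   dispersion; the working value is $\max(\phi_g, \phi(\mu_g))$
   (conservative sharing), floored at $10^{-8}$.
4. **Exact test.** Conditioning on the gene's total count $K$ across both
   groups, each split $(a, K-a)$ is scored by the product of the two
   group-sum NB densities (means $\hat q \sum_{j} s_j$ per side, variances
   $\hat q \sum s_j + \phi \hat q^2 \sum s_j^2$); the two-sided p-value
   sums the probabilities of all splits no more probable than the
   observed one, normalized by the total. A relative tolerance of
   $10^{-7}$ guards the inclusion of the observed split against floating
   point ties; the variance is floored just above the Poisson value so
   the NB size parameter stays finite as $\phi \to 0$, which also gives
   the correct Poisson/binomial limit.
5. **Calls.** Benjamini–Hochberg adjustment; "enriched in A" requires
   `padj < 0.1` *and* fold enrichment (ratio of normalized means) above
   1 — adjusted significance alone would also count depletions.

Zero-total genes get p = 1 by convention; a zero denominator with a
positive numerator reports fold enrichment `Inf`, which ranks first and
is legitimate (the gene is detected only in A).

The trend-fitting settings (parametric trend, conservative "maximum"
sharing) follow the documented defaults of the first-generation NB
differential expression tools this stage models; when exact historical
settings of a given published analysis are unknown, reproduction of its
gene lists can only be approximate, which is why the deposited-data check
on enriched-list sizes uses a ±10% band rather than exact equality.

## The resampling overlap test

Marker sets are first intersected with the filtered universe — genes that
never entered differential testing cannot overlap. For an enriched list
of size $n$ from a universe of $N$ genes containing $K$ marker genes, the
null distribution is built by drawing $n$ genes without replacement $B$
times (default 1000) and recording the overlap. With the resampling mean
$\hat m$ ("estimate") and $d = |\mathrm{obs} - \hat m|$, the two-sided
p-value is

$$p = \frac{\#\{x : x < \hat m - d\} + \#\{x : x > \hat m + d\}}{B},$$

with strict inequalities, so $p = 0$ is attainable and ties exactly at
$\hat m \pm d$ are excluded. This distance-based form is preserved
verbatim as the primary statistic for fidelity to the analysis it
reimplements; because it excludes the observed value's own probability
mass it is mildly anticonservative (asymptotic type-I rate ≈ 0.056 at
0.05 for the study-sized geometry), so the standard
$(\mathrm{count}+1)/(B+1)$ correction is reported alongside, as is the
exact two-sided hypergeometric p — the closed-form twin of the same null.
The 95% interval is the empirical 2.5/97.5 percentile band of the
resamples, and an overlap is flagged significant, with explicit
direction, when the observed count falls outside it. Draws are taken from
the universe in canonical (sorted) order so results are invariant to
input ordering, and all randomness is seed-derived.

## Rank-based logistic model and MDS

To ask whether stronger enrichment predicts layer membership, all genes
in the filtered universe are ranked by descending fold enrichment (rank
1 = strongest; ties broken by ascending adjusted p, then gene id), and
membership in a marker set is regressed on rank by a from-scratch IRLS
(Fisher scoring) logistic fit: convergence at coefficient changes below
$10^{-8}$ or 50 iterations, Wald inference from the inverse Fisher
information, and complete separation reported as a flagged non-converged
fit rather than an error. Ranking the full universe (not only the
enriched genes) gives the regression both classes along the whole rank
axis; a flag restricts to enriched genes for the narrower question.

Sample structure is summarized by classical (Torgerson) MDS on a
leading-fold-change distance: for each sample pair, the root mean square
of the 500 largest absolute log2 ratios of size-factor-normalized counts,
with a 0.5 pseudocount stabilizing zeros. The pairwise distances isolate
the genes that most distinguish each pair, which is what separates
purified populations from background in practice.

## Numerical and design choices

* **Seeding.** Every stochastic stage takes an explicit seed; stage seeds
  are derived from one run seed by a fixed integer mix (`derive_seed`),
  so a pipeline run is byte-reproducible and stages are decoupled. Counts
  are drawn gene-by-gene so extending a catalog appends draws without
  perturbing earlier genes.
* **Degenerate inputs.** All-zero genes: p = 1. Empty overlap partitions:
  percentage 0 with an explicit flag. A marker set disjoint from the
  universe warns rather than errors. A resampling null with zero variance
  (marker set = universe) is flagged degenerate.
* **Problem sizes in the shipped analyses.** The `analysis/` drivers and
  the acceptance script use a 5,000-gene universe with 3 replicates per
  type and six replicate simulations; this is large enough for stable
  sensitivity/FDR estimates (≈100 planted layer 2/3 markers per run)
  while keeping a full run in minutes.
* **Acceptance checks against deposited data.** Three checks reproduce
  headline numbers of the TU-tagging visual-cortex study this analysis
  models (filtered universe sizes,
  enriched-list sizes, set algebra between its two enriched lists); they
  require the study's supplementary tables, which are not redistributed
  here — see `data-raw/README.md`. They fail with an explanatory message
  when the files are absent.

## Known limitations

* The NB stage supports exactly the two-group exact-test design: no
  covariates, no GLM contrasts, no shrunken fold changes, no
  without-replicates mode.
* Reproduction of a historical analysis's exact gene lists depends on
  that software's version defaults; the conservative-sharing parametric
  trend used here is documented but not guaranteed identical.
* The simulator's truth labels ("expected fold > 1") are exact for its
  own mixture model; on real data no such labels exist and precision
  must be judged against curated marker sets, with all their curation
  noise.
* The distance-based resampling p is reported as published; users who
  need a strictly valid permutation p should read the corrected field.

## A minimal run

```{r example}
library(tutag)

report <- run_pipeline(list(
  simulation = list(n_genes = 2000, seed = 7),
  comparisons = list(c("Sepw1", "Nr5a1"), c("Sepw1", "WT")),
  seed = 7
), out_dir = "tutag_run")

report$comparisons$Sepw1_vs_Nr5a1$overlap
```

The same stages are exposed individually (`simulate_experiment()`,
`run_comparison()`, `overlap_test()`, `fit_logistic()`,
`mds_leading_foldchange()`), and the `analysis/` scripts at the
repository root run them as a narrated workflow.
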