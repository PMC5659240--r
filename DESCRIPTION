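Package: tutag
Title: Differential Enrichment Analysis for TU-Tagging RNA Purification Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cell-type-specific metabolic RNA labeling
    (TU-tagging) experiments in developing mouse cortex. Provides a
    negative-binomial exact test for differential enrichment between
    streptavidin-purified RNA sample types (counts-per-million low-count
    filtering, median-of-ratios normalization, dispersion estimation with a
    parametric mean trend), a resampling test for overlap between enriched
    gene lists and cortical layer-marker gene sets, a rank-based binomial
    logistic model of layer-membership probability, leading-fold-change
    multidimensional scaling of samples, and a synthetic count generator
    with known ground truth that models purification background carryover
    and transcription-rate/half-life labeling dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
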