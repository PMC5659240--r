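# Deposited study data (not redistributed)

Three acceptance checks in `tests/testthat/test-acceptance.R` reproduce
headline numbers from the study's deposited supplementary tables. Those
files are not shipped with this repository; to run the checks, download
them and convert to the following plain-text layouts in this directory:

- `table1_4_counts.tsv` — the deposited raw gene-count table (htseq
  counts, protein-coding genes): `gene_id` column plus one integer column
  per sample.
- `table1_4_samples.tsv` — two columns `sample_id`, `sample_type` with
  types `Sepw1`, `Nr5a1`, `WT` assigning the count columns.
- `table1_2_enriched.tsv` — the deposited Sepw1-vs-WT enriched gene list:
  columns `gene_id`, `fold_enrichment`.
- `table1_3_enriched.tsv` — the deposited Sepw1-vs-Nr5a1 enriched gene
  list: same columns.

Without these files the three checks report a failure explaining that the
deposited data are unavailable; all other tests are self-contained.
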