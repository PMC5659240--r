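#!/usr/bin/env Rscript

# Step 3: overlap of enriched lists with layer-marker sets.
#
# Resampling overlap test (1000 draws) of each enriched list against every
# planted layer set, with the distance-based two-sided p and the 95%
# percentile band; then the Venn partition of the two enriched lists
# scored for layer 2/3 content. Writes results/overlap/.

library(tutag)

sets <- read_gene_sets("results/simulation/layer_sets.gmt")
dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)

enriched <- list()
for (tag in c("Sepw1_vs_Nr5a1", "Sepw1_vs_WT")) {
  de <- utils::read.delim(file.path("results/de", paste0(tag, ".tsv")),
                          stringsAsFactors = FALSE)
  enriched[[tag]] <- de$gene_id[de$enriched]
  tab <- overlap_table(enriched[[tag]], de$gene_id, sets,
                       B = 1000, seed = 20170925 + nchar(tag))
  utils::write.table(tab, file.path("results/overlap", paste0(tag, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(tag, " (", length(enriched[[tag]]), " enriched):")
  for (r in seq_len(nrow(tab))) {
    flag <- if (tab$significant[r]) paste0(" *", tab$direction[r], " CI*") else ""
    message(sprintf("  %-12s overlap %3d expected %6.2f  p=%.3g%s",
                    tab$set_name[r], tab$observed_overlap[r],
                    tab$resample_mean[r], tab$p_resample[r], flag))
  }
}

v <- venn_partition(enriched[[1]], enriched[[2]], sets[["L2/3"]])
vdf <- data.frame(partition = names(v$sizes), size = as.vector(v$sizes),
                  pct_l23 = as.vector(v$pct_in_set))
utils::write.table(vdf, "results/overlap/venn_l23.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf(
  "Venn vs layer 2/3 set: only purified-vs-purified %d (%.1f%%), shared %d (%.1f%%), only background %d (%.1f%%)",
  v$sizes["only_a"], v$pct_in_set["only_a"], v$sizes["both"],
  v$pct_in_set["both"], v$sizes["only_b"], v$pct_in_set["only_b"]))
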