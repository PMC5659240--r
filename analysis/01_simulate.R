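#!/usr/bin/env Rscript

# Step 1: simulate a TU-tagging experiment with known ground truth.
#
# Three sample types (a layer 2/3-weighted Cre purification, a layer 4
# purification, and a no-UPRT background), 3 replicates each, over a
# 5,000-gene universe with 100 planted markers per patterned layer.
# Writes counts, sample sheet, truth table and config under
# results/simulation/.

library(tutag)

seed <- 20170925
cfg <- simulation_config(n_genes = 5000, seed = seed)
sim <- simulate_experiment(cfg)

paths <- write_simulation(sim, cfg, "results/simulation")
write_gene_sets(catalog_gene_sets(sim$catalog), "results/simulation/layer_sets.gmt")

tab <- table(sim$catalog$genes$home_layer)
message("simulated ", nrow(sim$counts), " genes x ", ncol(sim$counts), " samples")
message("planted markers per layer: ",
        paste(names(tab), tab, sep = "=", collapse = ", "))
message("median newly transcribed fraction over the ",
        cfg$labeling_window_h, "-h window: ",
        round(median(sim$truth$new_fraction), 3))
message("written: ", paste(basename(paths), collapse = ", "), ", layer_sets.gmt")
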