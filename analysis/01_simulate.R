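#!/usr/bin/env Rscript
# Stage 1 — simulate the study dataset.
#
# Twelve species on an ultrametric Yule tree (height 0.4 substitutions/site)
# split into two classes at the root, each genome carrying a BovB-like
# 3.2-kb LINE family evolved by copy-and-paste amplification, permanent
# inactivation and segmental-deletion decay, plus two planted cross-class
# horizontal transfer events late on recipient branches. The ground truth
# (every copy's location, ancestry and horizontal flag) is written alongside
# the genomes so later stages can be scored.

library(htscan)

seed <- 7
cfg <- validate_config(list(seed = seed))
st <- simulate_stage(cfg)

dir.create("results", showWarnings = FALSE)
write_simulation(st$sim, "results/sim", st$taxonomy)
write.table(st$ht_events, file.path("results/sim", "ht_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tr <- st$sim$truth
cat("simulated", length(st$sim$genomes), "genomes of",
    cfg$sim$background_genome_length, "bp\n")
cat("true TE copies:", nrow(tr),
    "| intact:", sum(tr$intact),
    "| horizontal:", sum(tr$horizontal), "\n")
cat("planted transfer events:\n")
print(st$ht_events)
cat("copies per species:\n")
print(table(tr$species))
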