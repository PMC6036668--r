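#!/usr/bin/env Rscript
# Stage 5 — horizontal-transfer detection and validation.
#
# Clusters spanning both classes become candidates; within each, copy-level
# mutual-best cross-class pairs are validated by the flank-contrast test
# (high identity must be restricted to the element), reciprocal best hits,
# scaffold quality, and phylogenetic discordance (NJ tree of the cluster +
# the pair sitting far below the species divergence). The confirmed pairs
# are compared against the planted events.

library(htscan)

copies <- read_copy_table("results/mine/copies.tsv")
clusters_tab <- read.delim("results/cluster/clusters.tsv")
clusters <- tibble::tibble(cluster_id = clusters_tab$cluster_id,
                           member_id = clusters_tab$member_id)
taxonomy <- read_taxonomy("results/sim/taxonomy.tsv")
species_tree <- read_newick("results/sim/species_tree.nwk")
genome_files <- list.files("results/sim", pattern = "^sp\\d+\\.fa$",
                           full.names = TRUE)
genomes <- vapply(genome_files, function(f) read_fasta(f)$seq[1], "")
names(genomes) <- sub("\\.fa$", "", basename(genome_files))

cfg <- validate_config(list(seed = 7))
report <- detect_ht(clusters, copies, genomes, taxonomy, species_tree,
                    rank = cfg$detect$rank,
                    flank_len = cfg$detect$flank_len,
                    flank_max = cfg$detect$flank_max,
                    margin = cfg$detect$margin,
                    support_max = cfg$detect$support_max,
                    discordance_margin = cfg$detect$discordance_margin)

dir.create("results/detect", showWarnings = FALSE)
write.table(report, "results/detect/ht_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(summarise_ht_report(report), "results/detect/ht_summary.txt")

cat("candidate cross-class pairs:", nrow(report), "\n")
writeLines(summarise_ht_report(report))

events <- read.delim("results/sim/ht_events.tsv")
truth_pairs <- sort(apply(events[, c("donor", "recipient")], 1,
                          function(x) paste(sort(x), collapse = "~")))
confirmed <- report[report$status == "confirmed", ]
found_pairs <- if (nrow(confirmed)) {
  sort(apply(confirmed[, c("species_a", "species_b")], 1,
             function(x) paste(sort(x), collapse = "~")))
} else character(0)
cat("planted events:   ", paste(truth_pairs, collapse = ", "), "\n")
cat("confirmed pairs:  ", paste(found_pairs, collapse = ", "), "\n")
cat("recovered:", length(intersect(truth_pairs, found_pairs)), "of",
    length(truth_pairs), "\n")
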