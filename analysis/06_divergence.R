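#!/usr/bin/env Rscript
# Stage 6 — Kimura divergence landscapes.
#
# Every mined copy is aligned back to the master element and its K2P
# distance accumulated (weighted by copy length) into 1% bins — the repeat
# landscape whose peaks mark amplification bursts relative to the family
# consensus.

library(htscan)

copies <- read_copy_table("results/mine/copies.tsv")
master <- read_fasta("results/sim/master.fa")$seq[1]

rows <- list()
for (sp in unique(copies$species)) {
  cp <- copies[copies$species == sp, ]
  ls <- divergence_landscape(cp, master)
  if (nrow(ls$profile) > 0) {
    prof <- ls$profile
    prof$species <- sp
    rows[[sp]] <- prof
    cat(sprintf("%-5s modal bin %2d%%, %6d bp in profile (%d copies excluded)\n",
                sp, landscape_modes(ls, 1), ls$included_bp, ls$n_excluded))
  }
}
land <- do.call(rbind, rows)
dir.create("results/divergence", showWarnings = FALSE)
write.table(land, "results/divergence/landscape.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# The landscapes are unimodal near the tree height: every lineage,
# transferred or not, is equally old relative to the ancestral master, so a
# transfer is invisible here — divergence profiles date amplification, not
# provenance. The transfer signal is the copy-to-copy distance across
# species, far below what vertical descent allows:
events <- read.delim("results/sim/ht_events.tsv")
for (i in seq_len(nrow(events))) {
  don <- copies[copies$species == events$donor[i], ]
  rec <- copies[copies$species == events$recipient[i], ]
  dmin <- min(vapply(seq_len(nrow(rec)), function(r) {
    min(vapply(seq_len(nrow(don)), function(d) {
      pair_k2p(rec$seq[r], don$seq[d], "cap")
    }, 1))
  }, 1))
  cat(sprintf("%s -> %s: closest cross-species copy pair at K2P %.3f (species divergence 0.8)\n",
              events$donor[i], events$recipient[i], dmin))
}
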