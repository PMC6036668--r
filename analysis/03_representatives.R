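#!/usr/bin/env Rscript
# Stage 3 — per-species representatives.
#
# Copies are annotated for intactness (family length bounds + a >= 200-aa
# open reading frame), then each species gets one representative: the
# centroid (longest intact copy within the 2-4 kb cut-offs) where one
# exists, otherwise a majority-rule cluster consensus. At the divergences
# simulated here most old copies have lost their long ORF, so the consensus
# route dominates — the same reason a consensus approach struggles on
# genuinely degraded families.

library(htscan)

copies <- read_copy_table("results/mine/copies.tsv")
cfg <- validate_config(list(seed = 7))
copies <- annotate_intact(copies, cfg$features$min_orf_aa)
write_copy_table(copies, "results/mine/copies.tsv")

reps <- list()
for (sp in unique(copies$species)) {
  cp <- copies[copies$species == sp, ]
  cen <- select_centroid(cp, cfg$features$centroid_min, cfg$features$centroid_max)
  if (!is.null(cen)) {
    cen$species <- sp
    reps[[sp]] <- cen
  } else {
    con <- build_consensus(cp, cfg$features$consensus_identity)
    if (nrow(con) > 0) {
      con <- con[which.max(con$n_supporting_copies), ]
      con$species <- sp
      reps[[sp]] <- con[, c("rep_id", "method", "seq",
                            "n_supporting_copies", "species")]
    }
  }
}
reps <- do.call(rbind, reps)

dir.create("results/features", showWarnings = FALSE)
write_fasta(tibble::tibble(id = paste0(reps$species, "_", reps$method),
                           desc = reps$rep_id, seq = reps$seq),
            "results/features/representatives.fa")

cat("intact copies:", sum(copies$intact), "of", nrow(copies), "\n")
cat("representatives by method:\n")
print(table(reps$method))

# RT-domain scan over the longest ORF of each representative
pssm <- build_pssm(rt_seed_alignment())
n_rt <- 0L
for (i in seq_len(nrow(reps))) {
  orfs <- find_orfs(reps$seq[i], min_aa_len = 200)
  if (nrow(orfs) == 0) next
  best <- orfs$aa_seq[which.max(nchar(orfs$aa_seq))]
  if (nrow(score_rt_domain(best, pssm)) > 0) n_rt <- n_rt + 1L
}
cat("representatives with a detectable RT domain:", n_rt, "of", nrow(reps), "\n")
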