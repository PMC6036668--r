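# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no data files.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Independent full-DP identity oracle (Biostrings Needleman-Wunsch with the
# same scoring), never the package's own aligner.
oracle_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2,
                                      type = "global")
  Biostrings::pid(pa, "PID1") / 100
}

# substitute exactly n sites (no multiple hits), uniform over alternatives
substitute_exact <- function(seq, n) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(v), n)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# a set of sequences from k planted masters
planted_families <- function(k, per_family, len, within_div, between_div) {
  base <- rnd_dna(len)
  masters <- vapply(seq_len(k), function(i) {
    if (i == 1) base else mutate_seq(base, between_div)
  }, character(1))
  seqs <- character(0)
  truth <- integer(0)
  for (f in seq_len(k)) {
    for (m in seq_len(per_family)) {
      seqs <- c(seqs, mutate_seq(masters[f], within_div / 2))
      truth <- c(truth, f)
    }
  }
  names(seqs) <- sprintf("f%d_m%d", truth, seq_along(truth))
  list(seqs = seqs, truth = truth, masters = masters)
}

# brute-force connected components over an explicit edge criterion (oracle
# for the union-find single-linkage engine)
brute_components <- function(seqs, threshold, min_overlap_fraction = 0.5) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      al <- align_pair(seqs[[i]], seqs[[j]], mode = "local")
      ok <- al$columns >= min_overlap_fraction * min(nchar(seqs[[i]]),
                                                     nchar(seqs[[j]])) &&
        al$identity >= threshold
      adj[i, j] <- adj[j, i] <- ok
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# a two-species contamination fixture: species B's TE region including both
# flanks is a verbatim copy of species A's (synthetic stand-in for an
# assembly-contamination case)
contamination_fixture <- function(seed = 42) {
  set.seed(seed)
  bovb <- canonical_te()
  gA <- paste0(rnd_dna(3000), bovb, rnd_dna(3000))
  region <- substr(gA, 2001, 2000 + 1000 + nchar(bovb) + 1000)
  gB <- paste0(rnd_dna(2500), region, rnd_dna(2500))
  lib <- tibble::tibble(id = "BovB", family = "BovB", seq = bovb)
  copies <- rbind(mine_genome(gA, lib, species = "spA"),
                  mine_genome(gB, lib, species = "spB"))
  list(genomes = c(spA = gA, spB = gB), copies = copies,
       taxonomy = tibble::tibble(species = c("spA", "spB"),
                                 phylum = c("phylum_A", "phylum_B"),
                                 class = c("class_A", "class_B"),
                                 order = c("order_A", "order_B")),
       tree = ape::read.tree(text = "(spA:0.4,spB:0.4);"))
}
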