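two_taxon_config <- function(seed, height = 0.25, amp = 1, inact = 0,
                             ht = NULL, n_init = 3L, genome = 100000L) {
  tr <- generate_species_tree(2, seed = seed, height = height)
  sim_config(tr, background_genome_length = genome, n_initial_copies = n_init,
             amplification_rate = amp, inactivation_prob = inact,
             ht_events = ht, seed = seed)
}

test_that("species tree generation is reproducible and well-formed", {
  t1 <- generate_species_tree(12, seed = 5, height = 0.4)
  t2 <- generate_species_tree(12, seed = 5, height = 0.4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(t1$Nnode, 11L)                       # 11 internal bifurcations
  depths <- ape::node.depth.edgelength(t1)[1:12]
  expect_true(all(abs(depths - 0.4) < 1e-9))        # ultrametric at height
  expect_error(generate_species_tree(1), ">= 2")
  cherry <- generate_species_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2L)
})

test_that("simulation is deterministic under a fixed seed", {
  s1 <- evolve(two_taxon_config(3))
  s2 <- evolve(two_taxon_config(3))
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero rates give master-identical copies at constant number", {
  s <- evolve(two_taxon_config(4, amp = 0))
  expect_equal(as.integer(table(s$truth$species)), rep(3L, 2))  # n_initial each
  expect_true(all(s$truth$seq != s$master))                 # substitutions ran
  cfg <- two_taxon_config(4, height = 0, amp = 0)
  cfg$tree$edge.length[] <- 0
  s0 <- evolve(cfg)
  expect_true(all(s0$truth$seq == s0$master))               # no time, no change
  expect_false(any(s0$truth$horizontal))
})

test_that("truth sequences always equal the strand-normalised genome slice", {
  s <- evolve(two_taxon_config(6, amp = 2))
  for (i in seq_len(nrow(s$truth))) {
    r <- s$truth[i, ]
    expect_identical(extract_interval(s$genomes[[r$species]], r$start, r$end,
                                      r$strand), r$seq)
  }
  s <- fragment(s, deletion_rate = 3, seed = 7)
  for (i in seq_len(nrow(s$truth))) {
    r <- s$truth[i, ]
    expect_identical(extract_interval(s$genomes[[r$species]], r$start, r$end,
                                      r$strand), r$seq)
  }
})

test_that("fragmentation is an identity transform at rate zero and marks decay", {
  s <- evolve(two_taxon_config(8, amp = 1))
  s0 <- fragment(s, deletion_rate = 0)
  expect_identical(s0$genomes, s$genomes)
  expect_identical(s0$truth, s$truth)

  sf <- fragment(s, deletion_rate = 5, min_intact_length = 2000, seed = 2)
  lens <- sf$truth$end - sf$truth$start
  expect_true(any(lens < nchar(s$master)))     # some copies actually shrank
  expect_identical(sf$truth$intact, lens >= 2000)

  # heavy decay with deletions the size of the copy leaves nothing intact
  sh <- fragment(s, deletion_rate = 20, deletion_size_range = c(3000L, 3000L),
                 min_intact_length = 2000, seed = 3)
  expect_true(any(!sh$truth$intact))
  expect_true(all((sh$truth$end - sh$truth$start) > 0))
})

test_that("amplification matches the birth-process mean over replicates", {
  amp <- 1.5; h <- 0.3; n0 <- 3
  counts <- vapply(1:50, function(i) {
    s <- evolve(two_taxon_config(100 + i, height = h, amp = amp, n_init = n0))
    sum(s$truth$species == "sp1")
  }, 1)
  expected <- n0 * exp(amp * h)
  vary <- n0 * exp(amp * h) * (exp(amp * h) - 1)
  se <- sqrt(vary / 50)
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("without HT no cross-species pair is spuriously similar", {
  # min cross-species K2P distance must not undercut the species divergence
  # by more than 3 sigma of the K2P estimate (estimated by the delta method
  # at d = 2 * height for the master length)
  h <- 0.25
  d <- 2 * h
  # empirical sigma of the K2P estimate at distance d for the master length
  set.seed(99)
  m <- canonical_te()
  reps <- vapply(1:40, function(i) {
    a <- mutate_seq(m, h); b <- mutate_seq(m, h)
    k2p(a, b)$K
  }, 1)
  sigma <- sd(reps)
  lower <- d - 3 * sigma
  for (seed in 1:20) {
    s <- evolve(two_taxon_config(500 + seed, height = h, amp = 0.5))
    a_ids <- which(s$truth$species == "sp1")
    b_ids <- which(s$truth$species == "sp2")
    dmin <- min(vapply(a_ids, function(i) {
      min(vapply(b_ids, function(j) {
        k2p(s$truth$seq[i], s$truth$seq[j])$K
      }, 1))
    }, 1))
    expect_gte(dmin, lower)
  }
})

test_that("planted HT produces copies closer to the donor than to the sister", {
  # 4 taxa; sp3's sister is sp1, so transfer from the distant sp2 late on
  # sp3's branch
  tr <- generate_species_tree(4, seed = 21, height = 0.3)
  ht <- data.frame(donor = "sp2", recipient = "sp3", time_frac = 0.9,
                   n_copies = 2L)
  cfg <- sim_config(tr, background_genome_length = 60000L,
                    n_initial_copies = 3L, amplification_rate = 1,
                    inactivation_prob = 0, ht_events = ht, seed = 22)
  s <- evolve(cfg)
  expect_gte(sum(s$truth$horizontal), 2L)
  hcp <- s$truth[s$truth$horizontal & s$truth$species == "sp3", ]
  don <- s$truth[s$truth$species == "sp2" & !s$truth$horizontal, ]
  spd <- ape::cophenetic.phylo(tr)
  sister <- names(which.min(spd["sp3", setdiff(colnames(spd), "sp3")]))
  expect_equal(sister, "sp1")
  sis <- s$truth[s$truth$species == sister, ]
  mean_k <- function(x, y) {
    mean(vapply(seq_len(nrow(x)), function(i) {
      mean(vapply(seq_len(nrow(y)), function(j) {
        al <- align_pair(x$seq[i], y$seq[j])
        k2p(al$a_aln, al$b_aln)$K
      }, 1))
    }, 1))
  }
  expect_lt(mean_k(hcp, don), mean_k(hcp, sis))
})

test_that("HT configuration is validated", {
  tr <- generate_species_tree(4, seed = 1, height = 0.3)
  expect_error(sim_config(tr, ht_events = data.frame(
    donor = "sp1", recipient = "sp1", time_frac = 0.5, n_copies = 1)))
  expect_error(sim_config(tr, ht_events = data.frame(
    donor = "sp1", recipient = "sp2", time_frac = 1.5, n_copies = 1)))
  expect_error(evolve(sim_config(tr, ht_events = data.frame(
    donor = "nope", recipient = "sp2", time_frac = 0.5, n_copies = 1),
    seed = 1)), "unknown tip")
})

test_that("simulation output writes the expected files", {
  s <- evolve(two_taxon_config(31, amp = 0.5))
  d <- withr::local_tempdir()
  write_simulation(s, d, taxonomy = tibble::tibble(
    species = c("sp1", "sp2"), phylum = "p", class = "c", order = "o"))
  expect_true(all(file.exists(file.path(
    d, c("sp1.fa", "sp2.fa", "truth.tsv", "species_tree.nwk", "master.fa",
         "taxonomy.tsv", "provenance.log")))))
  tt <- read_copy_table(file.path(d, "truth.tsv"))
  expect_equal(nrow(tt), nrow(s$truth))
})
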