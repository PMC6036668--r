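test_that("a verbatim planted query is recovered exactly on both strands", {
  set.seed(20)
  g <- rnd_dna(20000)
  q <- substr(g, 5001, 8200)
  h <- seed_extend_search(g, q)
  expect_equal(nrow(h), 1L)
  expect_equal(h$sstart, 5000L)
  expect_equal(h$send, 8200L)
  expect_equal(h$identity, 1)
  expect_equal(h$strand, "+")

  hm <- seed_extend_search(g, revcomp(q))
  expect_equal(hm$strand, "-")
  expect_equal(c(hm$sstart, hm$send), c(5000L, 8200L))

  expect_equal(nrow(seed_extend_search(rnd_dna(5000), rnd_dna(1000))), 0L)
})

test_that("divergent planted copies are recovered at calibrated identity", {
  # 10% uniform substitutions: recovered identity in [0.86, 0.94] and the
  # ungapped estimate never exceeds the full-DP oracle by more than 0.02
  set.seed(21)
  for (rep in 1:20) {
    q <- rnd_dna(1000)
    planted <- substitute_exact(q, 100)
    g <- paste0(rnd_dna(4000), planted, rnd_dna(4000))
    h <- seed_extend_search(g, q)
    m <- merge_hits(h, max_gap = 500)
    expect_gte(nrow(m), 1L)
    best <- m[which.max(m$score), ]
    expect_gte(best$identity, 0.86)
    expect_lte(best$identity, 0.94)
    o <- oracle_identity(extract_interval(g, best$sstart, best$send), q)
    expect_lte(best$identity - o, 0.02)
  }
})

test_that("hit merging respects gaps and strands", {
  h <- tibble::tibble(
    sstart = c(100L, 400L, 5600L), send = c(400L, 600L, 5900L),
    strand = "+", qstart = 0L, qend = 1L,
    length = c(300L, 200L, 300L), matches = c(300L, 150L, 300L),
    identity = c(1, 0.75, 1), score = c(600, 300, 600))
  m <- merge_hits(h, max_gap = 500)
  expect_equal(nrow(m), 2L)                   # gaps 0 and 5000 -> two loci
  expect_equal(m$send[1], 600L)
  expect_equal(m$identity[1], (300 * 1 + 200 * 0.75) / 500)

  h$strand <- c("+", "-", "+")
  m2 <- merge_hits(h, max_gap = 10000)
  expect_equal(nrow(m2), 2L)                  # opposite strands never merge
})

test_that("reciprocal best hit classifies, relabels and rejects", {
  set.seed(22)
  bovb <- canonical_te()
  l1 <- rnd_dna(3000)
  lib <- tibble::tibble(id = c("BovB", "L1"), family = c("BovB", "L1"),
                        seq = c(bovb, l1))
  r <- rbh_classify(mutate_seq(bovb, 0.05), lib, "BovB")
  expect_equal(r$family, "BovB")
  expect_true(r$confirmed)
  # locus mined with the BovB query whose best library hit is the other
  # family gets relabelled and unconfirmed
  r2 <- rbh_classify(mutate_seq(l1, 0.05), lib, "BovB")
  expect_equal(r2$family, "L1")
  expect_false(r2$confirmed)
  r3 <- rbh_classify(rnd_dna(1500), lib, "BovB")
  expect_equal(r3$family, "unclassified")
  expect_false(r3$confirmed)
})

test_that("flank extraction truncates at scaffold ends and follows strand", {
  g <- paste0(strrep("A", 50), strrep("C", 100), strrep("G", 30))
  copy <- list(start = 50L, end = 150L, strand = "+")
  f <- extract_flanks(copy, g, flank_len = 40)
  expect_equal(f$left, strrep("A", 40))
  expect_equal(f$right, strrep("G", 30))
  expect_true(f$truncated)

  copy0 <- list(start = 0L, end = 150L, strand = "+")
  f0 <- extract_flanks(copy0, g, flank_len = 40)
  expect_equal(f0$left, "")
  expect_true(f0$truncated)

  interior <- list(start = 60L, end = 100L, strand = "+")
  fi <- extract_flanks(interior, g, flank_len = 10)
  expect_false(fi$truncated)
  expect_equal(nchar(fi$left), 10L)

  # minus strand: left flank in copy orientation = revcomp of downstream
  fm <- extract_flanks(list(start = 60L, end = 100L, strand = "-"), g, 10)
  expect_equal(fm$left, revcomp(substr(g, 101, 110)))
  expect_equal(fm$right, revcomp(substr(g, 51, 60)))
})

test_that("mining simulated genomes recovers truth copies precisely", {
  tr <- generate_species_tree(3, seed = 30, height = 0.1)
  cfg <- sim_config(tr, background_genome_length = 60000L,
                    n_initial_copies = 3L, amplification_rate = 1,
                    inactivation_prob = 0, seed = 30)
  s <- evolve(cfg)
  lib <- tibble::tibble(id = "BovB", family = "BovB", seq = s$master)
  for (sp in names(s$genomes)) {
    copies <- mine_genome(s$genomes[[sp]], lib, species = sp)
    truth <- s$truth[s$truth$species == sp, ]
    overlaps <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))
    # recall: every truth copy overlapped by a mined locus
    rec <- vapply(seq_len(nrow(truth)), function(i) {
      any(overlaps(truth$start[i], truth$end[i], copies$start, copies$end) >
            0.5 * (truth$end[i] - truth$start[i]))
    }, TRUE)
    expect_true(all(rec))
    # precision: every locus overlaps a truth interval
    prec <- vapply(seq_len(nrow(copies)), function(i) {
      any(overlaps(copies$start[i], copies$end[i], truth$start, truth$end) > 0)
    }, TRUE)
    expect_true(all(prec))
    expect_true(all(copies$confirmed))
  }
})

test_that("chimeric loci are detected with the right nesting order", {
  set.seed(42)
  bovb <- canonical_te()
  l1 <- rnd_dna(3000)
  genome <- paste0(rnd_dna(5000), substr(bovb, 1, 1600), l1,
                   substr(bovb, 1601, 3200), rnd_dna(5000))
  lib <- tibble::tibble(id = c("BovB", "L1"), family = c("BovB", "L1"),
                        seq = c(bovb, l1))
  copies <- mine_genome(genome, lib, species = "cow")
  ch <- detect_chimeras(copies)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$outer_family, "BovB")
  expect_equal(ch$inner_family, "L1")
  expect_equal(ch$relation, "nested")

  # disjoint far-apart loci of different families -> none
  far <- tibble::tibble(copy_id = c("a", "b"), scaffold = "s",
                        start = c(0L, 50000L), end = c(3200L, 53000L),
                        family = c("BovB", "L1"))
  expect_equal(nrow(detect_chimeras(far)), 0L)
  # same-family overlap -> none
  same <- tibble::tibble(copy_id = c("a", "b"), scaffold = "s",
                         start = c(0L, 1000L), end = c(3200L, 4000L),
                         family = "BovB")
  expect_equal(nrow(detect_chimeras(same)), 0L)
})
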