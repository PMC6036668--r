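toy_taxonomy <- function() {
  tibble::tibble(
    species = c("cow", "yak", "bedbug", "viper"),
    phylum = c("Chordata", "Chordata", "Arthropoda", "Chordata"),
    class = c("Mammalia", "Mammalia", "Insecta", "Reptilia"),
    order = c("Artiodactyla", "Artiodactyla", "Hemiptera", "Squamata"))
}

test_that("cross-rank filtering keeps only rank-spanning clusters", {
  copies <- tibble::tibble(copy_id = paste0("c", 1:4),
                           species = c("cow", "yak", "cow", "bedbug"),
                           seq = "ACGT")
  tax <- toy_taxonomy()
  same <- tibble::tibble(cluster_id = "c_1", member_id = c("c1", "c2"))
  expect_equal(nrow(filter_cross_rank(same, copies, tax, "class")), 0L)

  cross <- tibble::tibble(cluster_id = "c_2", member_id = c("c3", "c4"))
  got <- filter_cross_rank(cross, copies, tax, "class")
  expect_equal(nrow(got), 1L)
  expect_setequal(c(got$rank_a, got$rank_b), c("Mammalia", "Insecta"))

  expect_equal(nrow(filter_cross_rank(same[0, ], copies, tax, "class")), 0L)
  bad <- tibble::tibble(cluster_id = "c_3", member_id = c("c1", "c4"))
  copies2 <- copies
  copies2$species[4] <- "martian"
  expect_error(filter_cross_rank(bad, copies2, tax, "class"), "martian")
})

test_that("flank contrast separates transfer, noise and contamination", {
  set.seed(70)
  mk <- function(s) list(left = s, right = s, truncated = FALSE)
  # independent backgrounds: noise-level identity passes
  fa <- mk(rnd_dna(800)); fb <- mk(rnd_dna(800))
  r <- flank_contrast_test(fa, fb, te_identity = 0.95)
  expect_true(r$flank_ok)
  expect_false(r$contamination)
  expect_lt(r$left_identity, 0.6)

  # copied flanks: contamination
  shared <- rnd_dna(800)
  r2 <- flank_contrast_test(mk(shared), mk(mutate_seq(shared, 0.01)),
                            te_identity = 0.95)
  expect_false(r2$flank_ok)
  expect_true(r2$contamination)

  # truncated flank demotes the scaffold
  fc <- list(left = "", right = rnd_dna(800), truncated = TRUE)
  r3 <- flank_contrast_test(fc, fb, te_identity = 0.95)
  expect_false(r3$scaffold_ok)
})

test_that("reciprocal best hits must land inside the candidate cluster", {
  set.seed(71)
  m <- rnd_dna(600)
  copies <- tibble::tibble(
    copy_id = c("a1", "b1", "b2"),
    species = c("spA", "spB", "spB"),
    seq = c(m, mutate_seq(m, 0.03), mutate_seq(m, 0.5)))
  clusters <- tibble::tibble(cluster_id = c("c_1", "c_1", "c_2"),
                             member_id = c("a1", "b1", "b2"))
  pair <- tibble::tibble(member_a = "a1", member_b = "b1",
                         species_a = "spA", species_b = "spB")
  expect_true(rbh_confirm(pair, copies, clusters))

  # partner's best hit in spB falls outside the cluster -> fail
  copies2 <- copies
  copies2$seq[3] <- m                       # b2 (cluster c_2) now the best hit
  expect_false(rbh_confirm(pair, copies2, clusters))

  pair2 <- tibble::tibble(member_a = "a1", member_b = "b1",
                          species_a = "spA", species_b = "spC")
  expect_false(rbh_confirm(pair2, copies, clusters))   # no partner copies
})

test_that("support score is zero for identical cross-class copies", {
  set.seed(72)
  m <- rnd_dna(800)
  members <- tibble::tibble(member_id = c("x1", "x2"),
                            species = c("cow", "bedbug"),
                            rank = c("Mammalia", "Insecta"))
  dmat <- matrix(0, 2, 2, dimnames = list(c("x1", "x2"), c("x1", "x2")))
  pair <- tibble::tibble(member_a = "x1", member_b = "x2",
                         species_a = "cow", species_b = "bedbug")
  tr <- ape::read.tree(text = "((cow:0.1,yak:0.1):0.3,(bedbug:0.2,viper:0.2):0.2);")
  sup <- score_ht_support(members, dmat, pair, tr)
  expect_equal(sup$support_score, 0)
  expect_true(is.na(sup$tree_discordant))              # < 4 members
})

test_that("reports are sorted, and confirmation requires every verdict", {
  rows <- list(
    tibble::tibble(cluster_id = "c_2", rank = "class", n_members = 5L,
                   member_a = "a", member_b = "b", species_a = "s1",
                   species_b = "s2", rank_a = "r1", rank_b = "r2",
                   te_identity = 0.9, flank_left_identity = 0.3,
                   flank_right_identity = 0.3, flank_ok = TRUE, rbh_ok = TRUE,
                   scaffold_ok = TRUE, tree_discordant = TRUE,
                   support_score = 0.4, status = "confirmed"),
    tibble::tibble(cluster_id = "c_1", rank = "class", n_members = 4L,
                   member_a = "c", member_b = "d", species_a = "s3",
                   species_b = "s4", rank_a = "r1", rank_b = "r2",
                   te_identity = 0.6, flank_left_identity = 0.2,
                   flank_right_identity = 0.2, flank_ok = TRUE, rbh_ok = FALSE,
                   scaffold_ok = TRUE, tree_discordant = FALSE,
                   support_score = 0.1, status = "rejected"))
  rep <- assemble_report(rows)
  expect_equal(rep$cluster_id, c("c_1", "c_2"))        # by support score
  expect_equal(nrow(assemble_report(list())), 0L)
  expect_match(summarise_ht_report(rep)[2], "confirmed")
  confirmed <- rep[rep$status == "confirmed", ]
  expect_true(all(confirmed$flank_ok & confirmed$rbh_ok &
                  confirmed$scaffold_ok & confirmed$tree_discordant))
})

test_that("a contamination fixture is demoted, never confirmed", {
  fx <- contamination_fixture()
  cl <- greedy_centroid_cluster(setNames(fx$copies$seq, fx$copies$copy_id), 0.55)
  rep <- detect_ht(cl, fx$copies, fx$genomes, fx$taxonomy, fx$tree)
  expect_gte(nrow(rep), 1L)
  expect_true(all(rep$status == "likely_contamination"))
  expect_false(any(rep$status == "confirmed"))
})

test_that("a copy at a scaffold edge demotes the candidate to artefact", {
  set.seed(73)
  bovb <- canonical_te()
  gA <- paste0(bovb, rnd_dna(3000))                    # copy at scaffold start
  gB <- paste0(rnd_dna(2500), mutate_seq(bovb, 0.02), rnd_dna(2500))
  lib <- tibble::tibble(id = "BovB", family = "BovB", seq = bovb)
  copies <- rbind(mine_genome(gA, lib, species = "spA"),
                  mine_genome(gB, lib, species = "spB"))
  cl <- greedy_centroid_cluster(setNames(copies$seq, copies$copy_id), 0.55)
  tax <- tibble::tibble(species = c("spA", "spB"),
                        phylum = c("pA", "pB"), class = c("cA", "cB"),
                        order = c("oA", "oB"))
  tr <- ape::read.tree(text = "(spA:0.4,spB:0.4);")
  rep <- detect_ht(cl, copies, c(spA = gA, spB = gB), tax, tr)
  expect_true(all(rep$status == "likely_artefact"))
  expect_false(any(rep$scaffold_ok))
})
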