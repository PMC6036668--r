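test_that("K2P matches the closed form and flags saturation", {
  expect_equal(k2p("ACGT", "ACGT")$K, 0)
  # 1000 sites, 100 transitions, 50 transversions: P=0.1, Q=0.05
  a <- strrep("A", 1000)
  bv <- rep("A", 1000); bv[1:100] <- "G"; bv[101:150] <- "C"
  r <- k2p(a, paste(bv, collapse = ""))
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$K, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)), tolerance = 1e-9)

  # saturation: P = 0.45, Q = 0.1 makes 1 - 2P - Q = 0
  cv <- rep("A", 1000); cv[1:450] <- "G"; cv[451:550] <- "T"
  expect_error(k2p(a, paste(cv, collapse = "")), "saturation")
  # gap/N columns are excluded
  r2 <- k2p("ACG-TN", "ACGATA")
  expect_equal(r2$sites, 4L)
})

test_that("K is at least P + Q (multiple-hit correction only inflates)", {
  set.seed(60)
  for (i in 1:20) {
    a <- rnd_dna(600)
    b <- mutate_seq(a, runif(1, 0.01, 0.4))
    r <- k2p(a, b)
    expect_gte(r$K, r$P + r$Q - 1e-12)
  }
})

test_that("progressive alignment handles base cases and projects faithfully", {
  set.seed(61)
  m <- rnd_dna(400)
  ident <- setNames(rep(m, 4), paste0("s", 1:4))
  msa0 <- align_progressive(ident)
  expect_true(all(msa0 == m))                            # gapless

  seqs <- setNames(vapply(1:6, function(i) mutate_seq(m, 0.05), ""),
                   paste0("s", 1:6))
  msa <- align_progressive(seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  M <- msa_int(msa)
  for (pair in list(c(1, 2), c(3, 5))) {
    direct <- pairwise_identity(seqs[[pair[1]]], seqs[[pair[2]]])
    proj <- msa_pair_identity(M, pair[1], pair[2])
    expect_lt(abs(direct - proj), 0.05)
  }
})

test_that("progressive alignment recovers homologous columns with deletions", {
  set.seed(62)
  m <- rnd_dna(500)
  mk <- function() {
    s <- mutate_seq(m, 0.05)
    # one deletion of 10-30 bp at a random interior position
    del <- sample(50:400, 1); w <- sample(10:30, 1)
    paste0(substr(s, 1, del), substr(s, del + w + 1, nchar(s)))
  }
  seqs <- setNames(c(m, vapply(1:5, function(i) mk(), "")), paste0("s", 1:6))
  msa <- align_progressive(seqs)
  # identity of each sequence to the ungapped master projection should stay
  # near the simulated divergence: misalignment would crush it
  M <- msa_int(msa)
  idents <- vapply(2:6, function(i) msa_pair_identity(M, 1, i), 1)
  expect_true(all(idents > 0.85))
})

test_that("conserved block extraction honours block size and gap policy", {
  msa <- c(s1 = "AAAAACCCCCGGGGG", s2 = "AAAAACCCCCGGGGG",
           s3 = "AAAAATTTTTGGGGG")
  expect_equal(unname(nchar(conserved_blocks(msa, min_block = 5)[1])), 15L)

  set.seed(63)
  alt <- vapply(1:4, function(i) {
    paste(vapply(1:40, function(j) {
      if (j %% 2) "A" else rnd_dna(1)
    }, ""), collapse = "")
  }, "")
  names(alt) <- paste0("s", 1:4)
  expect_warning(cb <- conserved_blocks(alt, min_block = 5,
                                        min_conserved_fraction = 0.9))
  expect_equal(unname(nchar(cb[1])), 0L)

  # one 20-column conserved block flanked by noise
  core <- strrep("ACGTA", 4)
  noisy <- vapply(1:4, function(i) paste0(rnd_dna(11), core, rnd_dna(11)), "")
  names(noisy) <- paste0("s", 1:4)
  cb2 <- conserved_blocks(noisy, min_block = 5, min_conserved_fraction = 0.9)
  expect_equal(unname(cb2[1]), core)

  # allow_gaps = "none" rejects gapped columns
  g <- c(a = "AAAAAAA-AA", b = "AAAAAAAAAA", c = "AAAAAAAAAA")
  expect_lt(nchar(conserved_blocks(g, allow_gaps = "none")[1]),
            nchar(conserved_blocks(g, allow_gaps = "all")[1]))
})

test_that("NJ recovers additive trees exactly and clamps negatives", {
  set.seed(64)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.5)
    d <- ape::cophenetic.phylo(tr)
    nt <- nj_tree(d)
    expect_equal(rf_distance(ape::unroot(tr), nt), 0L)
    expect_lt(max(abs(ape::cophenetic.phylo(nt)[rownames(d), colnames(d)] - d)),
              1e-9)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
  star <- nj_tree(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                         dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(length(star$tip.label), 3L)
  expect_true(all(star$edge.length >= 0))
})

test_that("RF distance counts discordant bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rf_distance(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t2), 2L)
  # brute-force bipartition oracle on random pairs (n <= 8)
  set.seed(65)
  biparts <- function(tr) {
    tr <- ape::unroot(tr)
    pp <- ape::prop.part(tr)
    sets <- lapply(pp, function(x) sort(tr$tip.label[x]))
    sets <- Filter(function(s) length(s) >= 2 &&
                     length(s) <= length(tr$tip.label) - 2, sets)
    canon <- vapply(sets, function(s) {
      comp <- sort(setdiff(tr$tip.label, s))
      paste(min(paste(s, collapse = ","), paste(comp, collapse = ",")))
    }, "")
    unique(canon)
  }
  for (i in 1:10) {
    a <- ape::rtree(sample(5:8, 1))
    b <- ape::rtree(length(a$tip.label))
    b$tip.label <- a$tip.label
    oracle <- length(union(setdiff(biparts(a), biparts(b)),
                           setdiff(biparts(b), biparts(a))))
    expect_equal(rf_distance(a, b), oracle)
  }
})

test_that("bootstrap supports are deterministic and resolve clean clades", {
  set.seed(66)
  m <- rnd_dna(600)
  m2 <- mutate_seq(m, 0.6)
  msa <- c(a1 = mutate_seq(m, 0.01), a2 = mutate_seq(m, 0.01),
           b1 = mutate_seq(m2, 0.01), b2 = mutate_seq(m2, 0.01))
  t1 <- bootstrap_nj(msa, n_reps = 100, seed = 9)
  t2 <- bootstrap_nj(msa, n_reps = 100, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0.95))                # focal split support

  tiny <- bootstrap_nj(msa, n_reps = 1, seed = 2)
  expect_true(all(tiny$node.label %in% c(0, 1)))
})

test_that("divergence landscapes bin coverage by Kimura distance", {
  set.seed(67)
  ref <- canonical_te()
  same <- tibble::tibble(copy_id = paste0("c", 1:5), seq = ref)
  ls <- divergence_landscape(same, ref)
  expect_equal(ls$profile$coverage_bp[1], 5 * nchar(ref))
  expect_equal(sum(ls$profile$coverage_bp), ls$included_bp)

  burst <- tibble::tibble(copy_id = paste0("b", 1:40),
                          seq = vapply(1:40, function(i) mutate_seq(ref, 0.10), ""))
  lb <- divergence_landscape(burst, ref)
  expect_equal(sum(lb$profile$coverage_bp), sum(nchar(burst$seq)))
  mode <- landscape_modes(lb, 1)
  expect_gte(mode, 9)
  expect_lte(mode, 11)
})
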