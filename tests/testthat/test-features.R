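test_that("consensus of identical copies is the copy itself", {
  set.seed(40)
  m <- rnd_dna(500)
  copies <- tibble::tibble(copy_id = paste0("c", 1:3), seq = m)
  cons <- build_consensus(copies, 0.9)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$seq, m)
  expect_equal(cons$n_supporting_copies, 3L)
  expect_false(cons$long_flag)
  expect_equal(nrow(build_consensus(copies[0, ], 0.9)), 0L)
})

test_that("majority consensus denoises independent errors", {
  # 5 copies with 2% independent noise: majority vote error <= 1% of length
  set.seed(41)
  m <- rnd_dna(800)
  copies <- tibble::tibble(copy_id = paste0("c", 1:5),
                           seq = vapply(1:5, function(i) mutate_seq(m, 0.02), ""))
  cons <- build_consensus(copies, 0.8)
  mm <- sum(strsplit(cons$seq[1], "")[[1]] != strsplit(m, "")[[1]])
  expect_lte(mm, 0.01 * nchar(m))
  # consensus never contains a character absent from every member column
  msa_chars <- unique(unlist(strsplit(copies$seq, "")))
  expect_true(all(strsplit(cons$seq[1], "")[[1]] %in% msa_chars))
})

test_that("degraded staggered copies yield a flagged over-long consensus", {
  # one full element plus overlapping 5' and 3' fragments: the stitched
  # consensus spans the full element, far longer than the typical member
  set.seed(42)
  m <- rnd_dna(3000)
  copies <- tibble::tibble(
    copy_id = paste0("c", 1:3),
    seq = c(mutate_seq(m, 0.05),
            mutate_seq(substr(m, 1, 2000), 0.05),
            mutate_seq(substr(m, 1001, 3000), 0.05)))
  cons <- build_consensus(copies, 0.7)
  expect_equal(nrow(cons), 1L)
  expect_true(cons$long_flag)
  expect_gt(nchar(cons$seq), 1.2 * 2000)
})

test_that("centroid selection applies the length cut-offs and tie-break", {
  mk <- function(lens, ids = paste0("c", seq_along(lens))) {
    set.seed(43)
    tibble::tibble(copy_id = ids, seq = vapply(lens, rnd_dna, ""))
  }
  expect_equal(select_centroid(mk(c(1500, 3100, 3900)))$rep_id, "c3")
  expect_null(select_centroid(mk(c(1500, 1900))))
  tie <- mk(c(3100, 3100), ids = c("beta", "alpha"))
  expect_equal(select_centroid(tie)$rep_id, "alpha")
  # intact flag excludes copies when present
  cp <- mk(c(3100, 3900))
  cp$intact <- c(TRUE, FALSE)
  expect_equal(select_centroid(cp)$rep_id, "c1")
})

test_that("ORF finding honours start-codon modes and frame completeness", {
  o <- find_orfs("ATGAAATAA", min_aa_len = 2, allow_nonstandard_starts = FALSE)
  expect_true("MK" %in% o$aa_seq)

  # 900 nt stop-free stretch without ATG: one ORF of >= 300 aa only in
  # non-standard mode
  set.seed(44)
  sense <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*" & Biostrings::GENETIC_CODE != "M"]
  stretch <- paste(sample(sense, 300, TRUE), collapse = "")
  s <- paste0("TAA", stretch, "TAA")
  o1 <- find_orfs(s, min_aa_len = 200, allow_nonstandard_starts = TRUE)
  expect_gte(sum(nchar(o1$aa_seq) >= 300), 1L)
  o2 <- find_orfs(s, min_aa_len = 200, allow_nonstandard_starts = FALSE)
  expect_equal(sum(o2$frame > 0 & grepl("^M", substr(o2$aa_seq, 1, 1)) &
                   nchar(o2$aa_seq) >= 300), 0L)

  # reverse complement gives mirrored coordinates
  m <- canonical_te()
  fw <- find_orfs(m, 200)
  rc <- find_orfs(revcomp(m), 200)
  expect_equal(sort(nchar(m) - fw$nt_end), sort(rc$nt_start))
  expect_setequal(rc$aa_seq, fw$aa_seq)
})

test_that("the master element carries one long ORF embedding the RT region", {
  o <- find_orfs(canonical_te(), 200)
  expect_equal(nrow(o), 1L)
  expect_gte(nchar(o$aa_seq), 900L)
  expect_true(grepl(rt_consensus_aa(), o$aa_seq, fixed = TRUE))
})

test_that("PSSM scoring finds true domains and rejects shuffled sequence", {
  pssm <- build_pssm(rt_seed_alignment())
  expect_equal(nrow(pssm), 220L)
  expect_equal(ncol(pssm), 20L)

  hit <- score_rt_domain(rt_consensus_aa(), pssm)
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(0L, 220L))

  # empirical null: shuffles never reach the default threshold
  set.seed(45)
  cons <- strsplit(rt_consensus_aa(), "")[[1]]
  for (i in 1:20) {
    sh <- paste(sample(cons), collapse = "")
    expect_equal(nrow(score_rt_domain(sh, pssm)), 0L)
  }
})

test_that("a diverged RT domain planted in junk is localised", {
  set.seed(46)
  aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  v <- strsplit(rt_consensus_aa(), "")[[1]]
  hit <- runif(220) < 0.3
  v[hit] <- sample(aa20, sum(hit), TRUE)
  junk <- function(n) paste(sample(aa20, n, TRUE), collapse = "")
  s <- paste0(junk(400), paste(v, collapse = ""), junk(380))
  pssm <- build_pssm(rt_seed_alignment())
  e <- score_rt_domain(s, pssm)
  expect_equal(nrow(e), 1L)
  jac <- (min(e$end, 620) - max(e$start, 400)) /
    (max(e$end, 620) - min(e$start, 400))
  expect_gte(jac, 0.8)
  expect_gte(e$end - e$start, 200L)
})

test_that("intactness requires family length bounds plus a long ORF", {
  bovb <- canonical_te()
  cp <- tibble::tibble(
    copy_id = c("full", "short", "noorf"),
    family = "BovB",
    seq = c(bovb, substr(bovb, 1, 1000), {
      set.seed(47); rnd_dna(3000)
    }))
  out <- annotate_intact(cp)
  expect_identical(out$intact, c(TRUE, FALSE, FALSE))
})
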