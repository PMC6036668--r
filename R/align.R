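# Pairwise alignment wrappers around the C++ kernels, and the identity
# definition used throughout the package: matches / alignment columns
# including internal gaps, excluding terminal gaps.

#' Default nucleotide alignment scoring
#'
#' Match +2 (the reward used for divergent-sequence searches), mismatch -3,
#' gap open -5, gap extend -2.
#' @return named list of scores.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2)
}

#' Indel-sparse scoring for distance estimation
#'
#' High gap-open, cheap gap-extension: gaps model rare segmental deletions
#' rather than micro-indels. Used when estimating substitution distances
#' (K2P) from pairwise alignments — permissive gap placement systematically
#' deflates distances between divergent sequences, because optimised gaps
#' absorb mismatch columns that the distance estimator then excludes.
#' @return named list of scores.
#' @export
distance_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = -20, gap_extend = -0.5)
}

#' K2P distance between two unaligned sequences
#'
#' Aligns with [distance_scoring()] (end-gap-free fit) and applies [k2p()].
#' @param a,b DNA strings.
#' @param on_saturation `"error"` or `"cap"`.
#' @param cap replacement distance under `"cap"`.
#' @return K2P distance (scalar).
#' @export
pair_k2p <- function(a, b, on_saturation = c("error", "cap"), cap = 3) {
  on_saturation <- match.arg(on_saturation)
  al <- align_pair(a, b, mode = "global", scoring = distance_scoring())
  tryCatch(k2p(al$a_aln, al$b_aln)$K, error = function(e) {
    if (on_saturation == "cap") cap else stop(e)
  })
}

#' Align two sequences
#'
#' Affine-gap pairwise alignment. `mode = "global"` is end-gap-free global
#' alignment with fit semantics: the shorter sequence is consumed in full and
#' only the longer sequence's terminal overhangs are free (ties broken by
#' string order, so the result is symmetric). `mode = "local"` is
#' Smith-Waterman. Identity is matches / alignment columns with internal
#' gaps counted and terminal gap runs excluded.
#'
#' @param a,b character scalars (same alphabet).
#' @param mode `"global"` or `"local"`.
#' @param scoring list as from [default_scoring()].
#' @return list with `a_aln`, `b_aln` (aligned core), `score`, `identity`,
#'   `matches`, `columns` (terminal gap runs excluded), `paired_columns`
#'   (both residues), and 0-based half-open core coordinates `a_start`,
#'   `a_end`, `b_start`, `b_end`.
#' @export
align_pair <- function(a, b, mode = c("global", "local"),
                       scoring = default_scoring()) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  swap <- nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)
  if (swap) { tmp <- a; a <- b; b <- tmp }
  r <- gotoh_align_cpp(a, b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend,
                       if (mode == "local") 1L else 0L)
  if (swap) {
    r <- list(a_aln = r$b_aln, b_aln = r$a_aln, score = r$score,
              a_start = r$b_start, a_end = r$b_end,
              b_start = r$a_start, b_end = r$a_end)
  }
  av <- if (nzchar(r$a_aln)) strsplit(r$a_aln, "", fixed = TRUE)[[1]] else character(0)
  bv <- if (nzchar(r$b_aln)) strsplit(r$b_aln, "", fixed = TRUE)[[1]] else character(0)
  core <- which(av != "-" & bv != "-")
  if (length(core) > 0) {
    keep <- core[1]:core[length(core)]       # trim terminal gap runs
    av <- av[keep]; bv <- bv[keep]
    r$matches <- sum(av == bv)
    r$columns <- length(keep)
    r$paired_columns <- sum(av != "-" & bv != "-")
    r$a_aln <- paste(av, collapse = "")
    r$b_aln <- paste(bv, collapse = "")
  } else {
    r$matches <- 0L
    r$columns <- 0L
    r$paired_columns <- 0L
    r$a_aln <- ""
    r$b_aln <- ""
  }
  r$identity <- if (r$columns > 0) r$matches / r$columns else 0
  r
}

#' Pairwise sequence identity
#'
#' Identity = matches / alignment columns (internal gaps counted, terminal
#' gaps excluded). Symmetric and in `[0, 1]`. `mode = "global"` uses
#' end-gap-free alignment; an alignment with zero aligned columns has
#' identity 0.
#'
#' @inheritParams align_pair
#' @return numeric fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, mode = c("global", "local"),
                              scoring = default_scoring()) {
  align_pair(a, b, match.arg(mode), scoring)$identity
}

#' Shared k-mer fraction distance between sequences
#'
#' 1 - |shared k-mers| / |k-mers of the smaller set|. Used to build MSA guide
#' trees and as an optional clustering prefilter.
#'
#' @param seqs character vector.
#' @param k word size.
#' @return symmetric distance matrix.
#' @export
kmer_distance <- function(seqs, k = 8L) {
  n <- length(seqs)
  sets <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        den <- min(length(sets[[i]]), length(sets[[j]]))
        sh <- if (den == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / den
        d[i, j] <- d[j, i] <- 1 - sh
      }
    }
  }
  rownames(d) <- colnames(d) <- names(seqs)
  d
}
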