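# Per-species representative construction (consensus / centroid), full-length
# filtering, ORF finding with non-standard starts, and PSSM-based
# reverse-transcriptase domain extraction.

#' Family full-length bounds
#'
#' Full-length nucleotide copies are >= 2.4 kb and < 4 kb for BovB,
#' >= 3 kb and < 9 kb for L1; unknown families get `default`.
#'
#' @param family family name.
#' @param default bounds for unknown families.
#' @return numeric `c(min, max)`; a copy is full-length when
#'   `min <= length < max`.
#' @export
family_length_bounds <- function(family, default = c(2400, 4000)) {
  switch(toupper(family),
         BOVB = c(2400, 4000),
         L1 = c(3000, 9000),
         default)
}

#' Filter copies to full length
#'
#' @param copies copies tibble with `family`, `seq`.
#' @return the full-length subset.
#' @export
filter_full_length <- function(copies) {
  len <- nchar(copies$seq)
  keep <- vapply(seq_len(nrow(copies)), function(i) {
    b <- family_length_bounds(copies$family[i])
    len[i] >= b[1] && len[i] < b[2]
  }, TRUE)
  copies[keep, , drop = FALSE]
}

#' Cluster-consensus representatives
#'
#' Clusters copies at `cluster_identity` (greedy centroid engine), aligns
#' each cluster progressively, and takes the majority-rule column consensus:
#' all-gap-majority columns are dropped, ties go to the base of the
#' first-seen member carrying a tied base. Clusters whose consensus is much
#' longer than the typical member (degraded/divergent copies) are flagged.
#'
#' @param copies tibble with `copy_id`, `seq` (one species/family).
#' @param cluster_identity greedy threshold in `[0.5, 1]` (representative
#'   construction uses 70-90%).
#' @param long_factor consensus/median-member length ratio that triggers the
#'   `long_flag`.
#' @return tibble: `rep_id`, `method`, `seq`, `n_supporting_copies`,
#'   `long_flag`; empty for no copies.
#' @export
build_consensus <- function(copies, cluster_identity = 0.8, long_factor = 1.2) {
  stopifnot(cluster_identity >= 0.5, cluster_identity <= 1)
  if (is.null(copies) || nrow(copies) == 0) {
    return(tibble(rep_id = character(0), method = character(0),
                  seq = character(0), n_supporting_copies = integer(0),
                  long_flag = logical(0)))
  }
  cl <- greedy_centroid_cluster(setNames(copies$seq, copies$copy_id),
                                threshold = cluster_identity)
  out <- list()
  for (cid in unique(cl$cluster_id)) {
    members <- cl$member_id[cl$cluster_id == cid]
    seqs <- setNames(copies$seq[match(members, copies$copy_id)], members)
    if (length(seqs) == 1) {
      cons <- unname(seqs[1])
    } else {
      msa <- align_progressive(seqs)
      m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
      cols <- character(0)
      for (j in seq_len(ncol(m))) {
        col <- m[, j]
        cnt <- table(col)
        if (names(cnt)[which.max(cnt)] == "-" ) next     # gap-majority dropped
        bases <- cnt[names(cnt) != "-"]
        top <- names(bases)[bases == max(bases)]
        if (length(top) > 1) {
          first <- col[col %in% top][1]                  # first-seen member wins
          top <- first
        }
        cols <- c(cols, top)
      }
      cons <- paste(cols, collapse = "")
    }
    out[[cid]] <- tibble(
      rep_id = cid, method = "consensus", seq = cons,
      n_supporting_copies = length(members),
      long_flag = nchar(cons) > long_factor * median(nchar(seqs)))
  }
  do.call(rbind, out)
}

#' Centroid representative: longest intact copy within length cut-offs
#'
#' The centroid is the longest intact copy with length in
#' `[min_len, max_len]` (2-kb minimum for intact elements; 4-kb maximum
#' guards against merged/overlapping elements). Ties break to the
#' lexicographically smallest `copy_id`.
#'
#' @param copies tibble with `copy_id`, `seq` and optionally `intact`.
#' @param min_len,max_len length cut-offs in bp.
#' @return one-row tibble (`rep_id`, `method`, `seq`, `n_supporting_copies`)
#'   or NULL when no copy qualifies.
#' @export
select_centroid <- function(copies, min_len = 2000L, max_len = 4000L) {
  if (is.null(copies) || nrow(copies) == 0) return(NULL)
  intact <- if ("intact" %in% names(copies)) copies$intact else TRUE
  len <- nchar(copies$seq)
  ok <- which(intact & len >= min_len & len <= max_len)
  if (length(ok) == 0) return(NULL)
  best <- ok[order(-len[ok], copies$copy_id[ok])][1]
  tibble(rep_id = copies$copy_id[best], method = "centroid",
         seq = copies$seq[best], n_supporting_copies = length(ok))
}

#' Find open reading frames on all six frames
#'
#' With non-standard starts allowed (the default, matching `-orfstyle 7`
#' behaviour), an ORF is any stop-free stretch of at least `min_aa_len`
#' codons ending at a stop codon or at the sequence end. In standard mode the
#' stretch must begin with ATG (counted from the Met).
#'
#' @param nt_seq DNA sequence.
#' @param min_aa_len minimum ORF length in amino acids.
#' @param allow_nonstandard_starts logical.
#' @return tibble: `frame` (+1..+3, -1..-3), `aa_start`, `aa_end` (0-based
#'   half-open on the frame translation), `nt_start`, `nt_end` (on the input,
#'   forward coordinates), `aa_seq`, `nt_seq`.
#' @export
find_orfs <- function(nt_seq, min_aa_len = 200L, allow_nonstandard_starts = TRUE) {
  L <- nchar(nt_seq)
  out <- list()
  for (dir in c(1L, -1L)) {
    s <- if (dir == 1L) nt_seq else revcomp(nt_seq)
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3
      if (ncod < min_aa_len) next
      sub <- substr(s, off + 1L, off + 3L * ncod)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X")))
      aav <- strsplit(aa, "", fixed = TRUE)[[1]]
      stops <- c(which(aav == "*"), length(aav) + 1L)
      prev <- 0L
      for (st in stops) {
        a0 <- prev          # 0-based start of stop-free stretch
        a1 <- st - 1L       # 0-based exclusive end
        prev <- st
        if (!allow_nonstandard_starts) {
          stretch <- aav[(a0 + 1L):a1]
          m <- which(stretch == "M")
          if (length(m) == 0) next
          a0 <- a0 + m[1] - 1L
        }
        if (a1 - a0 < min_aa_len) next
        nt0 <- off + 3L * a0          # on strand `s`, 0-based
        nt1 <- off + 3L * a1
        if (dir == 1L) {
          fs <- nt0; fe <- nt1
        } else {
          fs <- L - nt1; fe <- L - nt0
        }
        out[[length(out) + 1L]] <- tibble(
          frame = dir * (off + 1L), aa_start = a0, aa_end = a1,
          nt_start = fs, nt_end = fe,
          aa_seq = paste(aav[(a0 + 1L):a1], collapse = ""),
          nt_seq = substr(s, nt0 + 1L, nt1))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(frame = integer(0), aa_start = integer(0), aa_end = integer(0),
                  nt_start = integer(0), nt_end = integer(0),
                  aa_seq = character(0), nt_seq = character(0)))
  }
  do.call(rbind, out)
}

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Log2-odds of per-column residue frequencies (with pseudocounts) over a
#' uniform 1/20 background. Gap characters are ignored in the counts.
#'
#' @param seed_alignment character vector of equal-length aligned amino-acid
#'   sequences.
#' @param pseudocount added to every residue count per column.
#' @return numeric matrix, rows = alignment columns, columns = 20 residues.
#' @export
build_pssm <- function(seed_alignment, pseudocount = 1) {
  aa20 <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
  m <- do.call(rbind, strsplit(unname(seed_alignment), "", fixed = TRUE))
  W <- ncol(m)
  pssm <- matrix(0, W, 20, dimnames = list(NULL, aa20))
  for (j in seq_len(W)) {
    col <- m[, j]
    col <- col[col %in% aa20]
    cnt <- setNames(rep(pseudocount, 20), aa20)
    tb <- table(col)
    cnt[names(tb)] <- cnt[names(tb)] + tb
    pssm[j, ] <- log2((cnt / sum(cnt)) / 0.05)
  }
  pssm
}

#' Write / read a PSSM as a TSV matrix
#' @param pssm matrix from [build_pssm()].
#' @param path file path.
#' @export
write_pssm <- function(pssm, path) {
  write.table(pssm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Score reverse-transcriptase domains with a PSSM
#'
#' Ungapped local PSSM scan: for every diagonal offset the best-scoring
#' contiguous segment is found (maximum-subarray), and segments of at least
#' `min_len` residues with score >= `threshold` bits are reported as domain
#' envelopes. Overlapping envelopes are reduced to the best-scoring ones.
#' The default threshold sits far above the empirical null of shuffled
#' sequences (tens of bits) and far below a true domain hit (hundreds).
#'
#' @param aa_seq amino-acid sequence.
#' @param pssm matrix from [build_pssm()].
#' @param min_len minimum envelope length in residues (200 aa).
#' @param threshold minimum envelope score in bits.
#' @return tibble: `start`, `end` (0-based half-open on `aa_seq`), `score`.
#' @export
score_rt_domain <- function(aa_seq, pssm, min_len = 200L, threshold = 120) {
  aa20 <- colnames(pssm)
  v <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  idx <- match(v, aa20)
  W <- nrow(pssm)
  L <- length(v)
  found <- list()
  if (L >= min_len) {
    for (d in (-(W - 1L)):(L - 1L)) {
      # pssm row k aligns to seq position k + d (1-based k, 0-based d)
      ks <- max(1L, 1L - d):min(W, L - d)
      if (length(ks) < min_len) next
      sc <- vapply(ks, function(k) {
        ai <- idx[k + d]
        if (is.na(ai)) -1 else pssm[k, ai]
      }, 1)
      # maximum subarray (Kadane) with positions
      best <- -Inf; cur <- 0; cs <- 1L; bs <- 1L; be <- 0L
      for (i in seq_along(sc)) {
        if (cur <= 0) { cur <- sc[i]; cs <- i } else cur <- cur + sc[i]
        if (cur > best) { best <- cur; bs <- cs; be <- i }
      }
      if (best >= threshold && (be - bs + 1L) >= min_len) {
        s0 <- ks[bs] + d - 1L     # 0-based on aa_seq
        found[[length(found) + 1L]] <- tibble(
          start = s0, end = ks[be] + d, score = best)
      }
    }
  }
  if (length(found) == 0) {
    return(tibble(start = integer(0), end = integer(0), score = numeric(0)))
  }
  env <- do.call(rbind, found)
  env <- env[order(-env$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(env))
  for (i in seq_len(nrow(env))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(env))) {
      if (j == i || !keep[j]) next
      ov <- min(env$end[i], env$end[j]) - max(env$start[i], env$start[j])
      if (ov > 0 && env$score[j] <= env$score[i]) keep[j] <- FALSE
    }
  }
  env <- env[keep, , drop = FALSE]
  env[order(env$start), , drop = FALSE]
}

#' Annotate copy intactness
#'
#' A copy is intact when its length is within the family full-length bounds
#' and it carries at least one ORF of `min_aa_len` amino acids (the length
#' criterion plus a coding-capacity criterion).
#'
#' @param copies copies tibble with `family`, `seq`.
#' @param min_aa_len ORF length criterion.
#' @return `copies` with an `intact` logical column.
#' @export
annotate_intact <- function(copies, min_aa_len = 200L) {
  copies$intact <- vapply(seq_len(nrow(copies)), function(i) {
    b <- family_length_bounds(copies$family[i])
    len <- nchar(copies$seq[i])
    if (len < b[1] || len >= b[2]) return(FALSE)
    nrow(find_orfs(copies$seq[i], min_aa_len)) > 0
  }, TRUE)
  copies
}
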