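# Distance and tree machinery: Kimura two-parameter distances, progressive
# MSA, conserved-block extraction, neighbour joining with bootstrap, tree
# comparison, and divergence landscapes.

#' Kimura two-parameter distance from an aligned pair
#'
#' Columns containing a gap or `N` in either sequence are excluded. With
#' transition fraction `P` and transversion fraction `Q`,
#' `K = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param a,b aligned strings of equal length.
#' @return list with `P`, `Q`, `K` and `sites` (columns used).
#' @export
k2p <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  use <- av %in% .ht_bases & bv %in% .ht_bases
  n <- sum(use)
  if (n == 0) stop("no comparable sites")
  av <- av[use]; bv <- bv[use]
  diff <- av != bv
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diff & (purine[av] == purine[bv])   # A<->G, C<->T
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P saturation: substitution fractions outside the model domain (P = ",
         signif(P, 4), ", Q = ", signif(Q, 4), ")")
  }
  list(P = P, Q = Q, K = -0.5 * log(w1 * sqrt(w2)), sites = n)
}

#' Integer-encode a multiple alignment
#'
#' Rows are sequences, columns alignment positions; A,C,G,T -> 0..3 and
#' gap/N -> NA. Shared by the distance and identity helpers.
#' @param msa named character vector of equal-length aligned sequences.
#' @return integer matrix with sequence names as rownames.
#' @export
msa_int <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  out <- matrix(match(m, .ht_bases) - 1L, nrow = nrow(m))
  rownames(out) <- names(msa)
  out
}

k2p_from_counts <- function(n, nts, ntv, on_saturation, cap) {
  if (n == 0) {
    if (on_saturation == "cap") return(cap)
    stop("no comparable sites")
  }
  P <- nts / n
  Q <- ntv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    if (on_saturation == "cap") return(cap)
    stop("K2P saturation (P = ", signif(P, 4), ", Q = ", signif(Q, 4), ")")
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix from a multiple alignment
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param on_saturation `"error"` to propagate saturation errors, `"cap"` to
#'   replace saturated distances with `cap` (used by the bootstrap, where a
#'   resampled replicate may saturate even if the original alignment does not).
#' @param cap replacement distance under `"cap"`.
#' @return symmetric matrix with zero diagonal.
#' @export
k2p_matrix <- function(msa, on_saturation = c("error", "cap"), cap = 3) {
  on_saturation <- match.arg(on_saturation)
  M <- if (is.matrix(msa)) msa else msa_int(msa)
  n <- nrow(M)
  stopifnot(n >= 2)
  purine <- M == 0L | M == 2L
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      use <- !is.na(M[i, ]) & !is.na(M[j, ])
      diff <- use & (M[i, ] != M[j, ])
      ts <- sum(diff & (purine[i, ] == purine[j, ]))
      d[i, j] <- d[j, i] <- k2p_from_counts(sum(use), ts, sum(diff) - ts,
                                            on_saturation, cap)
    }
  }
  d
}

#' Pairwise identity of two rows of a multiple alignment
#'
#' Projection-based approximation of [pairwise_identity()]: columns where
#' both rows are gaps are dropped, terminal gap runs excluded, identity =
#' matches / remaining columns.
#' @param M integer matrix from [msa_int()].
#' @param i,j row indices or names.
#' @return fraction in `[0, 1]`.
#' @export
msa_pair_identity <- function(M, i, j) {
  a <- M[i, ]; b <- M[j, ]
  keep <- !(is.na(a) & is.na(b))
  a <- a[keep]; b <- b[keep]
  core <- which(!is.na(a) & !is.na(b))
  if (length(core) == 0) return(0)
  idx <- core[1]:core[length(core)]
  sum(a[idx] == b[idx], na.rm = TRUE) / length(idx)
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile progressive alignment along a UPGMA guide tree built from
#' shared 8-mer distances. Deterministic given input order.
#'
#' @param seqs named character vector of DNA sequences (length >= 1).
#' @param match,mismatch,gap profile column scores (soft mismatch/gap
#'   penalties suit divergent TE copies).
#' @return named character vector of aligned sequences (equal lengths).
#' @export
align_progressive <- function(seqs, match = 2, mismatch = -1, gap = -2.5) {
  n <- length(seqs)
  stopifnot(n >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  if (n == 1) return(seqs)

  as_mat <- function(s) matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
  profile_of <- function(m) {
    # 5 x L frequency matrix, rows A,C,G,T,gap (N spread uniformly over bases)
    L <- ncol(m)
    p <- matrix(0, 5, L)
    for (r in seq_len(nrow(m))) {
      idx <- match(m[r, ], c(.ht_bases, "-"))
      isN <- is.na(idx)
      for (x in which(!isN)) p[idx[x], x] <- p[idx[x], x] + 1
      if (any(isN)) p[1:4, isN] <- p[1:4, isN] + 0.25
    }
    p / nrow(m)
  }
  merge_two <- function(ma, mb) {
    al <- profile_align_cpp(profile_of(ma), profile_of(mb), match, mismatch, gap)
    L <- length(al$ia)
    out <- matrix("-", nrow(ma) + nrow(mb), L)
    out[seq_len(nrow(ma)), al$ia > 0] <- ma[, al$ia[al$ia > 0], drop = FALSE]
    out[nrow(ma) + seq_len(nrow(mb)), al$ib > 0] <- mb[, al$ib[al$ib > 0], drop = FALSE]
    out
  }

  if (n == 2) {
    groups <- list(as_mat(seqs[[1]]), as_mat(seqs[[2]]))
    members <- list(1L, 2L)
    res <- merge_two(groups[[1]], groups[[2]])
    ord <- c(1L, 2L)
  } else {
    hc <- hclust(as.dist(kmer_distance(unname(seqs))), method = "average")
    groups <- lapply(seqs, as_mat)
    members <- as.list(seq_len(n))
    node_group <- vector("list", nrow(hc$merge))
    node_members <- vector("list", nrow(hc$merge))
    pick <- function(k) {
      if (k < 0) list(g = groups[[-k]], m = members[[-k]])
      else list(g = node_group[[k]], m = node_members[[k]])
    }
    for (s in seq_len(nrow(hc$merge))) {
      a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
      node_group[[s]] <- merge_two(a$g, b$g)
      node_members[[s]] <- c(a$m, b$m)
    }
    res <- node_group[[nrow(hc$merge)]]
    ord <- node_members[[nrow(hc$merge)]]
  }
  aligned <- apply(res, 1, paste, collapse = "")
  out <- character(n)
  out[ord] <- aligned
  names(out) <- names(seqs)
  out
}

#' Project a pair of rows out of a multiple alignment
#'
#' Drops columns where both sequences are gaps; used to compare MSA-implied
#' pairwise identities with direct pairwise alignment.
#' @param msa named character vector (aligned).
#' @param i,j row names or indices.
#' @return list of two equal-length strings.
#' @export
msa_project_pair <- function(msa, i, j) {
  av <- strsplit(msa[[i]], "", fixed = TRUE)[[1]]
  bv <- strsplit(msa[[j]], "", fixed = TRUE)[[1]]
  keep <- !(av == "-" & bv == "-")
  list(a = paste(av[keep], collapse = ""), b = paste(bv[keep], collapse = ""))
}

#' Extract conserved blocks from a multiple alignment
#'
#' A column is conserved when its majority character (gaps not counted as the
#' majority character) reaches `min_conserved_fraction` of the sequences.
#' Maximal runs of at least `min_block` conserved columns are kept. With
#' `allow_gaps = "all"` (the setting used throughout), gap-containing columns
#' may be kept; with `"none"` any gap disqualifies a column.
#'
#' @param msa named character vector of aligned sequences.
#' @param min_block minimum run length (default 5).
#' @param allow_gaps `"all"` or `"none"`.
#' @param min_conserved_fraction majority-frequency threshold.
#' @return named character vector (possibly zero-width, with a warning).
#' @export
conserved_blocks <- function(msa, min_block = 5L, allow_gaps = c("all", "none"),
                             min_conserved_fraction = 0.5) {
  allow_gaps <- match.arg(allow_gaps)
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  L <- ncol(m)
  conserved <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    bases <- col[col != "-"]
    if (length(bases) == 0) next
    if (allow_gaps == "none" && any(col == "-")) next
    conserved[j] <- max(table(bases)) / nrow(m) >= min_conserved_fraction
  }
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  keep <- logical(L)
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_block) {
      keep[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
    }
  }
  if (!any(keep)) warning("no conserved blocks retained")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (length(out) == 0) out <- rep("", nrow(m))
  names(out) <- names(msa)
  out
}

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration; negative branch lengths are clamped to zero
#' with the deficit moved to the sibling branch at the same node.
#'
#' @param d symmetric distance matrix with labels (n >= 3).
#' @return unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("non-finite distances")
  tr <- ape::nj(d)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    sib <- which(tr$edge[, 1] == tr$edge[e, 1] & seq_len(nrow(tr$edge)) != e)
    if (length(sib) > 0) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ tree
#' for each replicate, and annotates the reference tree's internal nodes with
#' the fraction of replicates containing each bipartition.
#'
#' @param msa named character vector of aligned sequences (>= 4).
#' @param n_reps replicates (the analysis default is 1000).
#' @param seed RNG seed (deterministic supports for a given seed).
#' @return the reference NJ tree with `node.label` = support fractions.
#' @export
bootstrap_nj <- function(msa, n_reps = 1000L, seed = 1L) {
  stopifnot(length(msa) >= 4)
  M <- msa_int(msa)
  stopifnot(ncol(M) >= 2)
  ref <- nj_tree(k2p_matrix(M, on_saturation = "cap"))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    reps[[r]] <- nj_tree(k2p_matrix(M[, cols, drop = FALSE],
                                    on_saturation = "cap"))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_reps
  ref
}

#' Robinson-Foulds distance between two trees
#'
#' Count of bipartitions present in exactly one of the two unrooted trees.
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return integer.
#' @export
rf_distance <- function(t1, t2) {
  as.integer(phangorn::RF.dist(t1, t2))
}

#' Kimura divergence landscape
#'
#' Aligns each copy to a family reference (end-gap-free), computes the K2P
#' distance, and accumulates the copy's length into 1-unit (percent) K bins.
#' Copies with less than `min_aligned_fraction` of their length aligned, and
#' copies whose alignment is K2P-saturated, are excluded and counted.
#'
#' @param copies tibble with `copy_id`, `seq` (and optionally `species`,
#'   `family`), or a named character vector.
#' @param reference reference/consensus sequence for the family.
#' @param bin_width bin width in Kimura percent units.
#' @param min_aligned_fraction minimum aligned fraction of the copy.
#' @return list with `profile` (tibble `bin_start`, `bin_end`, `coverage_bp`),
#'   `n_excluded`, `included_bp`.
#' @export
divergence_landscape <- function(copies, reference, bin_width = 1,
                                 min_aligned_fraction = 0.5) {
  if (is.character(copies)) {
    copies <- tibble(copy_id = names(copies), seq = unname(copies))
  }
  ks <- numeric(0)
  lens <- integer(0)
  n_excl <- 0L
  for (i in seq_len(nrow(copies))) {
    s <- copies$seq[i]
    al <- align_pair(s, reference, mode = "global")
    if (al$paired_columns / nchar(s) < min_aligned_fraction) {
      n_excl <- n_excl + 1L
      next
    }
    k <- tryCatch(k2p(al$a_aln, al$b_aln)$K, error = function(e) NA_real_)
    if (is.na(k)) { n_excl <- n_excl + 1L; next }
    ks <- c(ks, 100 * k)
    lens <- c(lens, nchar(s))
  }
  if (length(ks) == 0) {
    prof <- tibble(bin_start = numeric(0), bin_end = numeric(0),
                   coverage_bp = numeric(0))
    return(list(profile = prof, n_excluded = n_excl, included_bp = 0))
  }
  nb <- floor(max(ks) / bin_width) + 1L
  edges <- (seq_len(nb) - 1L) * bin_width
  cov <- numeric(nb)
  idx <- pmin(floor(ks / bin_width) + 1L, nb)
  for (i in seq_along(idx)) cov[idx[i]] <- cov[idx[i]] + lens[i]
  list(profile = tibble(bin_start = edges, bin_end = edges + bin_width,
                        coverage_bp = cov),
       n_excluded = n_excl, included_bp = sum(lens))
}

#' Modal bins of a divergence profile
#'
#' Returns the bin starts of up to `n_modes` local coverage maxima separated
#' by at least `min_separation` percent, highest coverage first.
#' @param landscape result of [divergence_landscape()].
#' @param n_modes number of modes to report.
#' @param min_separation minimum distance between reported modes (percent).
#' @return numeric vector of bin starts.
#' @export
landscape_modes <- function(landscape, n_modes = 1L, min_separation = 5) {
  prof <- landscape$profile
  ord <- order(prof$coverage_bp, decreasing = TRUE)
  modes <- numeric(0)
  for (i in ord) {
    b <- prof$bin_start[i]
    if (prof$coverage_bp[i] == 0) break
    if (all(abs(b - modes) >= min_separation)) modes <- c(modes, b)
    if (length(modes) == n_modes) break
  }
  modes
}
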