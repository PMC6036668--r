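# TE mining: seeded local alignment of a family query against a genome,
# hit merging into loci, reciprocal-best-hit family classification against a
# repeat library, flank extraction, and chimeric-locus detection.

#' Seed-and-extend homology search
#'
#' Exact-word seeds on both strands with ungapped x-drop extension (a single
#' nucleotide searcher standing in for a dual protein/nucleotide strategy).
#' Coordinates are 0-based half-open on the forward genome strand; for
#' minus-strand hits `qstart`/`qend` refer to the original query.
#'
#' @param genome genome/scaffold sequence (character scalar).
#' @param query family query sequence.
#' @param word_size exact seed length (>= 8).
#' @param x_drop score drop that terminates extension.
#' @param min_identity minimum hit identity.
#' @param min_length minimum hit length in bp (fragments below this are noise
#'   on random background).
#' @param scoring list as from [default_scoring()] (only match/mismatch used).
#' @return tibble: `sstart`, `send`, `strand`, `qstart`, `qend`, `length`,
#'   `matches`, `identity`, `score`.
#' @export
seed_extend_search <- function(genome, query, word_size = 11L, x_drop = 50,
                               min_identity = 0.5, min_length = 100L,
                               scoring = default_scoring()) {
  stopifnot(word_size >= 8L)
  run_strand <- function(q, strand) {
    h <- seed_hits_cpp(genome, q, word_size, x_drop,
                       scoring$match, scoring$mismatch,
                       min_length, min_identity)
    h <- as_tibble(h)
    if (nrow(h) == 0) return(h)
    if (strand == "-") {
      qlen <- nchar(q)
      qs <- qlen - h$qend
      h$qend <- qlen - h$qstart
      h$qstart <- qs
    }
    h$strand <- strand
    h
  }
  plus <- run_strand(query, "+")
  minus <- run_strand(revcomp(query), "-")
  hits <- rbind(plus, minus)
  if (nrow(hits) == 0) {
    return(tibble(sstart = integer(0), send = integer(0), strand = character(0),
                  qstart = integer(0), qend = integer(0), length = integer(0),
                  matches = integer(0), identity = numeric(0), score = numeric(0)))
  }
  hits$identity <- hits$matches / hits$length
  hits <- hits[!duplicated(hits[, c("sstart", "send", "strand")]), , drop = FALSE]
  hits <- hits[order(hits$strand, hits$sstart, hits$send), , drop = FALSE]
  as_tibble(hits[, c("sstart", "send", "strand", "qstart", "qend",
                     "length", "matches", "identity", "score")])
}

#' Merge hits into loci
#'
#' Same-strand hits (to the same family query) whose genomic gap is at most
#' `max_gap` are chained into one locus; locus identity is the
#' alignment-length-weighted mean of member identities.
#'
#' @param hits tibble from [seed_extend_search()] (sorted or not).
#' @param max_gap maximum genomic gap in bp.
#' @return tibble: `sstart`, `send`, `strand`, `n_hits`, `length`,
#'   `identity`, `score`.
#' @export
merge_hits <- function(hits, max_gap = 500L) {
  if (nrow(hits) == 0) {
    return(tibble(sstart = integer(0), send = integer(0), strand = character(0),
                  n_hits = integer(0), length = integer(0), identity = numeric(0),
                  score = numeric(0)))
  }
  out <- list()
  for (st in unique(hits$strand)) {
    h <- hits[hits$strand == st, , drop = FALSE]
    h <- h[order(h$sstart, h$send), , drop = FALSE]
    cs <- h$sstart[1]; ce <- h$send[1]
    idx <- 1L
    members <- list()
    flush <- function(cs, ce, rows) {
      tibble(sstart = cs, send = ce, strand = st, n_hits = nrow(rows),
             length = sum(rows$length),
             identity = sum(rows$identity * rows$length) / sum(rows$length),
             score = sum(rows$score))
    }
    cur <- h[1, , drop = FALSE]
    if (nrow(h) > 1) {
      for (i in 2:nrow(h)) {
        if (h$sstart[i] - ce <= max_gap) {
          ce <- max(ce, h$send[i])
          cur <- rbind(cur, h[i, , drop = FALSE])
        } else {
          out[[length(out) + 1L]] <- flush(cs, ce, cur)
          cs <- h$sstart[i]; ce <- h$send[i]
          cur <- h[i, , drop = FALSE]
        }
      }
    }
    out[[length(out) + 1L]] <- flush(cs, ce, cur)
  }
  res <- do.call(rbind, out)
  res[order(res$sstart, res$send), , drop = FALSE]
}

#' Reciprocal-best-hit family classification
#'
#' Aligns a mined locus against every record of the repeat library
#' (end-gap-free); the best-scoring record's family is the label, and the
#' classification is `confirmed` when that family equals the family of the
#' query the locus was mined with. Loci whose best library identity falls
#' below `min_identity` are labelled `"unclassified"`.
#'
#' @param locus_seq locus sequence (element orientation).
#' @param repeat_library tibble with `id`, `family`, `seq`.
#' @param mined_family family label of the mining query.
#' @param min_identity minimum acceptable identity to the best library hit
#'   (the default sits above the ~0.52 end-gap-free alignment background of
#'   unrelated sequence).
#' @return list: `family`, `confirmed`, `best_id`, `identity`.
#' @export
rbh_classify <- function(locus_seq, repeat_library, mined_family,
                         min_identity = 0.6) {
  stopifnot(nrow(repeat_library) > 0)
  best <- NULL
  for (i in seq_len(nrow(repeat_library))) {
    al <- align_pair(locus_seq, repeat_library$seq[i], mode = "global")
    if (is.null(best) || al$score > best$score) {
      best <- list(score = al$score, identity = al$identity,
                   id = repeat_library$id[i], family = repeat_library$family[i])
    }
  }
  if (best$identity < min_identity) {
    return(list(family = "unclassified", confirmed = FALSE,
                best_id = NA_character_, identity = best$identity))
  }
  list(family = best$family, confirmed = identical(best$family, mined_family),
       best_id = best$id, identity = best$identity)
}

#' Extract the flanking regions of a copy
#'
#' Up to `flank_len` bp on each side, truncated at scaffold ends with a
#' truncation flag (candidates on short/truncated scaffolds are later
#' demoted). Flanks are reported in copy orientation: for a minus-strand copy
#' the left flank is the reverse complement of the genomic downstream side.
#'
#' @param copy one-row copies tibble (or list) with `start`, `end`, `strand`.
#' @param genome scaffold sequence.
#' @param flank_len flank length in bp.
#' @return list: `left`, `right`, `truncated` (logical).
#' @export
extract_flanks <- function(copy, genome, flank_len = 1000L) {
  stopifnot(flank_len > 0)
  G <- nchar(genome)
  up_s <- max(0L, copy$start - flank_len)
  up <- if (copy$start > 0) substr(genome, up_s + 1L, copy$start) else ""
  dn_e <- min(G, copy$end + flank_len)
  dn <- if (copy$end < G) substr(genome, copy$end + 1L, dn_e) else ""
  truncated <- nchar(up) < flank_len || nchar(dn) < flank_len
  if (copy$strand == "+") {
    list(left = up, right = dn, truncated = truncated)
  } else {
    list(left = if (nzchar(dn)) revcomp(dn) else "",
         right = if (nzchar(up)) revcomp(up) else "",
         truncated = truncated)
  }
}

#' Mine TE copies from a genome
#'
#' Runs [seed_extend_search()] + [merge_hits()] for every family in the
#' library, classifies each locus by reciprocal best hit, and returns a copies
#' table. Same-family overlapping loci are deduplicated (best score wins);
#' different-family overlaps are retained for chimera detection.
#'
#' @param genome scaffold sequence.
#' @param repeat_library tibble with `id`, `family`, `seq` (one mining query
#'   per family: the family consensus).
#' @param species,scaffold labels recorded on the copies.
#' @param params list of search parameters (see [seed_extend_search()] and
#'   `max_gap` for [merge_hits()]).
#' @return copies tibble: `copy_id`, `species`, `scaffold`, `start`, `end`,
#'   `strand`, `family`, `confirmed`, `identity_to_query`, `seq`.
#' @export
mine_genome <- function(genome, repeat_library, species = "sp", scaffold = "scf1",
                        params = list()) {
  p <- modifyList(list(word_size = 11L, x_drop = 50, min_identity = 0.5,
                       min_length = 100L, max_gap = 500L,
                       rbh_min_identity = 0.6), params)
  fams <- unique(repeat_library$family)
  loci <- list()
  for (fam in fams) {
    q <- repeat_library$seq[match(fam, repeat_library$family)]
    hits <- seed_extend_search(genome, q, p$word_size, p$x_drop,
                               p$min_identity, p$min_length)
    if (nrow(hits) == 0) next
    m <- merge_hits(hits, p$max_gap)
    m$family <- fam
    loci[[fam]] <- m
  }
  if (length(loci) == 0) {
    return(tibble(copy_id = character(0), species = character(0),
                  scaffold = character(0), start = integer(0), end = integer(0),
                  strand = character(0), family = character(0),
                  confirmed = logical(0), identity_to_query = numeric(0),
                  seq = character(0)))
  }
  loci <- do.call(rbind, loci)

  # same-family overlap dedup, best score first
  keep <- rep(TRUE, nrow(loci))
  ord <- order(-loci$score)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    for (jj in seq_along(ord)) {
      j <- ord[jj]
      if (j == i || !keep[j] || loci$family[j] != loci$family[i]) next
      ov <- min(loci$send[i], loci$send[j]) - max(loci$sstart[i], loci$sstart[j])
      if (ov > 0.5 * (loci$send[j] - loci$sstart[j]) && loci$score[j] <= loci$score[i]) {
        keep[j] <- FALSE
      }
    }
  }
  loci <- loci[keep, , drop = FALSE]
  loci <- loci[order(loci$sstart, loci$send), , drop = FALSE]

  n <- nrow(loci)
  out <- tibble(
    copy_id = sprintf("%s_m%04d", species, seq_len(n)), species = species,
    scaffold = scaffold, start = loci$sstart, end = loci$send,
    strand = loci$strand, family = loci$family, confirmed = NA,
    identity_to_query = loci$identity,
    seq = vapply(seq_len(n), function(i) {
      extract_interval(genome, loci$sstart[i], loci$send[i], loci$strand[i])
    }, character(1)))
  for (i in seq_len(n)) {
    cl <- rbh_classify(out$seq[i], repeat_library, out$family[i],
                       p$rbh_min_identity)
    out$confirmed[i] <- cl$confirmed
    if (!cl$confirmed && cl$family != "unclassified") out$family[i] <- cl$family
    if (cl$family == "unclassified") out$family[i] <- "unclassified"
  }
  out
}

#' Detect chimeric loci
#'
#' Reports different-family loci on the same scaffold that overlap or abut
#' within `max_gap`. An element inserted inside another typically splits the
#' host into two same-family loci sandwiching the insert; such triples are
#' reported once as `nested` (host family contains insert family, the
#' rearranged cattle-genome pattern). A locus whose span contains a
#' different-family locus is also `nested`; remaining abutting or partially
#' overlapping pairs are `adjacent`.
#'
#' @param loci copies/loci tibble with `scaffold`, `start`, `end`, `family`
#'   (and optionally `copy_id`).
#' @param max_gap maximum separation in bp for "abutting".
#' @return tibble: `scaffold`, `outer_id`, `inner_id`, `outer_family`,
#'   `inner_family`, `relation` (`nested` or `adjacent`).
#' @export
detect_chimeras <- function(loci, max_gap = 100L) {
  out <- list()
  empty <- tibble(scaffold = character(0), outer_id = character(0),
                  inner_id = character(0), outer_family = character(0),
                  inner_family = character(0), relation = character(0))
  if (nrow(loci) < 2) return(empty)
  ids <- if ("copy_id" %in% names(loci)) loci$copy_id else
    sprintf("locus%03d", seq_len(nrow(loci)))
  near <- function(i, j) {   # gap between spans (negative when overlapping)
    max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j])
  }
  consumed <- matrix(FALSE, nrow(loci), nrow(loci))
  # sandwich: same-family loci l and r split by a different-family insert i
  for (i in seq_len(nrow(loci))) {
    lefts <- which(loci$scaffold == loci$scaffold[i] &
                     loci$family != loci$family[i] &
                     loci$end <= loci$start[i] + max_gap &
                     loci$end > loci$start[i] - max_gap)
    rights <- which(loci$scaffold == loci$scaffold[i] &
                      loci$family != loci$family[i] &
                      loci$start >= loci$end[i] - max_gap &
                      loci$start < loci$end[i] + max_gap)
    for (l in lefts) {
      for (r in rights) {
        if (l == r || loci$family[l] != loci$family[r]) next
        out[[length(out) + 1L]] <- tibble(
          scaffold = loci$scaffold[i], outer_id = ids[l], inner_id = ids[i],
          outer_family = loci$family[l], inner_family = loci$family[i],
          relation = "nested")
        consumed[min(l, i), max(l, i)] <- TRUE
        consumed[min(r, i), max(r, i)] <- TRUE
      }
    }
  }
  for (i in 1:(nrow(loci) - 1)) {
    for (j in (i + 1):nrow(loci)) {
      if (consumed[i, j]) next
      if (loci$scaffold[i] != loci$scaffold[j]) next
      if (loci$family[i] == loci$family[j]) next
      if (near(i, j) > max_gap) next
      contained_ji <- loci$start[j] >= loci$start[i] && loci$end[j] <= loci$end[i]
      contained_ij <- loci$start[i] >= loci$start[j] && loci$end[i] <= loci$end[j]
      if (contained_ji) {
        o <- i; n <- j; rel <- "nested"
      } else if (contained_ij) {
        o <- j; n <- i; rel <- "nested"
      } else {
        o <- if (loci$start[i] <= loci$start[j]) i else j
        n <- if (o == i) j else i
        rel <- "adjacent"
      }
      out[[length(out) + 1L]] <- tibble(
        scaffold = loci$scaffold[i], outer_id = ids[o], inner_id = ids[n],
        outer_family = loci$family[o], inner_family = loci$family[n],
        relation = rel)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}
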