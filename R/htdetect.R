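# Turning clusters into validated HT candidates: cross-rank filtering,
# flank-contrast testing, reciprocal-best-hit confirmation, scaffold-quality
# demotion, and a phylogenetic support score. A candidate is confirmed only
# when every verdict passes; high flank identity demotes it to likely
# contamination, truncated scaffolds to likely artefact.

#' Filter clusters to those spanning a taxonomic rank
#'
#' Keeps clusters whose member species span at least two distinct values at
#' `rank` (class or phylum) and emits every cross-rank member pair. Vertical
#' inheritance dominates same-rank clusters; divergent-rank co-clustering is
#' the first HT signal.
#'
#' @param clusters long cluster tibble (`cluster_id`, `member_id`).
#' @param copies copies tibble mapping `copy_id` to `species`.
#' @param taxonomy taxonomy tibble (`species`, `phylum`, `class`, `order`).
#' @param rank `"class"` or `"phylum"`.
#' @return tibble of cross-rank pairs: `cluster_id`, `member_a`, `member_b`,
#'   `species_a`, `species_b`, `rank_a`, `rank_b`.
#' @export
filter_cross_rank <- function(clusters, copies, taxonomy,
                              rank = c("class", "phylum")) {
  rank <- match.arg(rank)
  if (nrow(clusters) == 0) {
    return(tibble(cluster_id = character(0), member_a = character(0),
                  member_b = character(0), species_a = character(0),
                  species_b = character(0), rank_a = character(0),
                  rank_b = character(0)))
  }
  sp <- copies$species[match(clusters$member_id, copies$copy_id)]
  missing <- setdiff(unique(sp), taxonomy$species)
  if (length(missing) > 0) {
    stop("species missing from taxonomy: ", paste(missing, collapse = ", "))
  }
  rk <- taxonomy[[rank]][match(sp, taxonomy$species)]
  out <- list()
  for (cid in unique(clusters$cluster_id)) {
    i <- which(clusters$cluster_id == cid)
    if (length(unique(rk[i])) < 2) next
    for (x in seq_along(i)) {
      for (y in seq_along(i)) {
        if (y <= x) next
        a <- i[x]; b <- i[y]
        if (rk[a] == rk[b]) next
        out[[length(out) + 1L]] <- tibble(
          cluster_id = cid,
          member_a = clusters$member_id[a], member_b = clusters$member_id[b],
          species_a = sp[a], species_b = sp[b],
          rank_a = rk[a], rank_b = rk[b])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(cluster_id = character(0), member_a = character(0),
                  member_b = character(0), species_a = character(0),
                  species_b = character(0), rank_a = character(0),
                  rank_b = character(0)))
  }
  do.call(rbind, out)
}

#' Flank-contrast test for a candidate pair
#'
#' True HT leaves high identity restricted to the TE itself: the flanks come
#' from unrelated genomic backgrounds and align at noise level. High
#' flank-to-flank identity approaching the TE identity signals contamination
#' or an orthologous region instead.
#'
#' @param flanks_a,flanks_b results of [extract_flanks()] for the two
#'   copies (lists with `left`, `right`, `truncated`).
#' @param te_identity pairwise identity of the two TE copies.
#' @param flank_max maximum acceptable flank identity (conservatively above
#'   the ~0.25 per-base expectation of unrelated 4-letter sequence under
#'   end-gap-free alignment, well below contamination-level identity).
#' @param margin contamination margin: flank identity within `margin` of the
#'   TE identity marks the pair as likely contamination.
#' @return list: `flank_ok`, `contamination`, `scaffold_ok`,
#'   `left_identity`, `right_identity`.
#' @export
flank_contrast_test <- function(flanks_a, flanks_b, te_identity,
                                flank_max = 0.6, margin = 0.1) {
  fid <- function(x, y) {
    if (!nzchar(x) || !nzchar(y)) return(0)
    pairwise_identity(x, y, mode = "global")
  }
  li <- fid(flanks_a$left, flanks_b$left)
  ri <- fid(flanks_a$right, flanks_b$right)
  # contamination needs flank identity both above alignment noise and within
  # margin of the TE identity: background-level flanks on a low-identity TE
  # pair are uninformative, not contamination
  list(flank_ok = li <= flank_max && ri <= flank_max,
       contamination = max(li, ri) > flank_max &&
         max(li, ri) >= te_identity - margin,
       scaffold_ok = !flanks_a$truncated && !flanks_b$truncated,
       left_identity = li, right_identity = ri)
}

#' Reciprocal-best-hit confirmation of a candidate pair
#'
#' Each copy is searched against the partner species' full copy set; the
#' pairing is confirmed when both best hits fall inside the candidate
#' cluster.
#'
#' @param pair one row of the [filter_cross_rank()] output.
#' @param copies copies tibble (`copy_id`, `species`, `seq`).
#' @param clusters long cluster tibble.
#' @return logical.
#' @export
rbh_confirm <- function(pair, copies, clusters) {
  cluster_of <- setNames(clusters$cluster_id, clusters$member_id)
  cid <- unname(cluster_of[pair$member_a])
  best_hit <- function(query_id, target_species) {
    q <- copies$seq[match(query_id, copies$copy_id)]
    targets <- copies[copies$species == target_species, , drop = FALSE]
    if (nrow(targets) == 0) return(NA_character_)
    sc <- vapply(targets$seq, function(s) align_pair(q, s, "global")$score, 1)
    targets$copy_id[which.max(sc)]
  }
  ba <- best_hit(pair$member_a, pair$species_b)
  bb <- best_hit(pair$member_b, pair$species_a)
  if (is.na(ba) || is.na(bb)) return(FALSE)
  isTRUE(unname(cluster_of[ba]) == cid) && isTRUE(unname(cluster_of[bb]) == cid)
}

#' HT support score and phylogenetic discordance
#'
#' `support_score` is the K2P distance of the candidate cross-rank pair
#' divided by the median within-rank K2P distance of the older clade (the
#' rank group with the larger internal median; vertical families accumulate
#' within-rank diversity that a recent transfer lacks, so scores below 1
#' support HT). `tree_discordant` captures the classic discordance signal —
#' on the TE tree the two species look far closer than the species tree
#' allows — with two jointly required conditions: (i) in the NJ tree of the cluster the pair groups together to
#' the exclusion of every same-rank copy that is species-tree closer than
#' the partner, and (ii) the pair's K2P distance is below
#' `discordance_margin` times the species-tree divergence of the two species
#' — vertically inherited copies in different species are at least as
#' divergent as the species themselves (deep TE lineage sorting only adds
#' distance), so only a transferred copy can sit well below that bound.
#'
#' @param members tibble (`member_id`, `species`, `rank`) for the cluster.
#' @param dmat K2P distance matrix over `member_id`.
#' @param pair one row of [filter_cross_rank()] output.
#' @param species_tree [ape::phylo] tree containing the member species.
#' @param discordance_margin fraction of the species divergence the pair's
#'   K2P distance must stay below (margin against K2P estimation noise).
#' @param pair_dist optional direct K2P distance of the pair (from
#'   [pair_k2p()]); the MSA-projected `dmat[a, b]` is used when NULL.
#' @return list: `support_score`, `tree_discordant` (NA below 4 members),
#'   `denominator`.
#' @export
score_ht_support <- function(members, dmat, pair, species_tree,
                             discordance_margin = 0.75, pair_dist = NULL) {
  a <- pair$member_a; b <- pair$member_b
  # the pair's own distance is numerically critical: prefer a direct
  # indel-sparse estimate over the MSA projection when supplied
  num <- if (!is.null(pair_dist)) pair_dist else dmat[a, b]
  meds <- c()
  for (r in unique(members$rank)) {
    ids <- members$member_id[members$rank == r]
    if (length(ids) >= 2) {
      sub <- dmat[ids, ids]
      meds[r] <- median(sub[upper.tri(sub)])
    }
  }
  spd <- ape::cophenetic.phylo(species_tree)
  den <- if (length(meds) > 0) max(meds) else spd[pair$species_a, pair$species_b]
  score <- if (den > 0) num / den else if (num == 0) 0 else Inf

  discordant <- NA
  too_close <- num < discordance_margin * spd[pair$species_a, pair$species_b]
  if (nrow(members) >= 4) {
    tr <- nj_tree(dmat[members$member_id, members$member_id])
    pp <- ape::prop.part(tr)
    sides <- lapply(pp, function(x) tr$tip.label[x])
    sides <- c(sides, lapply(sides, function(s) setdiff(tr$tip.label, s)))
    rank_of <- setNames(members$rank, members$member_id)
    sp_of <- setNames(members$species, members$member_id)
    check <- function(x, y) {
      dxy <- spd[sp_of[[x]], sp_of[[y]]]
      # copies from other species of x's rank that are species-tree closer
      # to x than the partner; x's own conspecific copies do not count (the
      # transferred lineage legitimately nests inside the donor species)
      closer <- members$member_id[
        members$rank == rank_of[[x]] & members$species != sp_of[[x]] &
          spd[members$species, sp_of[[x]]] < dxy]
      if (length(closer) == 0) return(FALSE)
      for (s in sides) {
        if (x %in% s && y %in% s && !any(closer %in% s)) return(TRUE)
      }
      FALSE
    }
    discordant <- (check(a, b) || check(b, a)) && too_close
  }
  list(support_score = unname(score), tree_discordant = discordant,
       denominator = unname(den))
}

#' Validate cross-rank candidates and assemble the HT report
#'
#' For every cluster spanning the rank: picks the highest-identity cross-rank
#' pair, runs the flank-contrast, reciprocal-best-hit, scaffold and
#' phylogenetic checks, scores support, and assigns a status. `confirmed`
#' requires every verdict to pass and `support_score < 1`.
#'
#' @param clusters long cluster tibble.
#' @param copies copies tibble (with `seq`, `species`, `scaffold`, `start`,
#'   `end`, `strand`).
#' @param genomes named character vector of scaffold sequences per species
#'   (single-scaffold genomes).
#' @param taxonomy taxonomy tibble.
#' @param species_tree [ape::phylo] species tree.
#' @param rank `"class"` or `"phylum"`.
#' @param flank_len flank length in bp.
#' @param flank_max,margin see [flank_contrast_test()].
#' @param support_max maximum support score for confirmation.
#' @param discordance_margin see [score_ht_support()].
#' @return HT report tibble, one row per candidate cluster, sorted by
#'   `support_score`.
#' @export
detect_ht <- function(clusters, copies, genomes, taxonomy, species_tree,
                      rank = "class", flank_len = 1000L,
                      flank_max = 0.6, margin = 0.1, support_max = 1,
                      discordance_margin = 0.75) {
  pairs <- filter_cross_rank(clusters, copies, taxonomy, rank)
  report <- list()
  for (cid in unique(pairs$cluster_id)) {
    member_ids <- clusters$member_id[clusters$cluster_id == cid]
    members <- tibble(
      member_id = member_ids,
      species = copies$species[match(member_ids, copies$copy_id)])
    members$rank <- taxonomy[[rank]][match(members$species, taxonomy$species)]

    msa <- align_progressive(
      setNames(copies$seq[match(member_ids, copies$copy_id)], member_ids))
    M <- msa_int(msa)
    dmat <- if (length(member_ids) >= 2) {
      k2p_matrix(M, on_saturation = "cap")
    } else matrix(0, 1, 1, dimnames = list(member_ids, member_ids))

    # species-level cross-rank similarity from MSA-projected copy identities:
    # for each cross-rank species pair, the best copy pair
    pp <- pairs[pairs$cluster_id == cid, , drop = FALSE]
    pp$identity <- vapply(seq_len(nrow(pp)), function(i) {
      msa_pair_identity(M, pp$member_a[i], pp$member_b[i])
    }, 1)
    # candidate pairs are copy-level mutual best partners: each copy's best
    # cross-rank partner copy, kept when the choice is reciprocal. A
    # transferred lineage always points at its true donor, so echo pairs
    # (recipient x relatives of the donor) fail mutuality, while two
    # transfers that share a recipient species remain separable
    all_members <- unique(c(pp$member_a, pp$member_b))
    best_partner <- vapply(all_members, function(m) {
      rows <- which(pp$member_a == m | pp$member_b == m)
      r <- rows[which.max(pp$identity[rows])]
      if (pp$member_a[r] == m) pp$member_b[r] else pp$member_a[r]
    }, character(1))
    mutual_rows <- which(vapply(seq_len(nrow(pp)), function(i) {
      identical(unname(best_partner[pp$member_a[i]]), pp$member_b[i]) &&
        identical(unname(best_partner[pp$member_b[i]]), pp$member_a[i])
    }, TRUE))
    cand <- pp[mutual_rows, , drop = FALSE]
    if (nrow(cand) > 1) {                    # one candidate per species pair
      spkey <- paste(pmin(cand$species_a, cand$species_b),
                     pmax(cand$species_a, cand$species_b))
      keep <- vapply(split(seq_len(nrow(cand)), spkey), function(ix) {
        ix[which.max(cand$identity[ix])]
      }, 1L)
      cand <- cand[sort(keep), , drop = FALSE]
    }
    cand$pair_dist <- vapply(seq_len(nrow(cand)), function(i) {
      pair_k2p(copies$seq[match(cand$member_a[i], copies$copy_id)],
               copies$seq[match(cand$member_b[i], copies$copy_id)],
               on_saturation = "cap")
    }, 1)
    if (nrow(cand) > 1) {
      # merge echoes: when a transfer's founders split their best-partner
      # votes between the true donor and a close relative, the resulting
      # pairs share a species whose copies are one cohort (their mutual
      # distance is of the order of the transfer distances, not of a second
      # independent event). Keep the highest-identity pair per event.
      ord <- order(-cand$identity)
      accept <- logical(nrow(cand))
      for (i in ord) {
        ok <- TRUE
        for (j in which(accept)) {
          shared <- intersect(c(cand$species_a[i], cand$species_b[i]),
                              c(cand$species_a[j], cand$species_b[j]))
          for (s in shared) {
            xi <- if (cand$species_a[i] == s) cand$member_a[i] else cand$member_b[i]
            xj <- if (cand$species_a[j] == s) cand$member_a[j] else cand$member_b[j]
            dcoh <- if (xi == xj) 0 else dmat[xi, xj]
            if (dcoh <= 2 * max(cand$pair_dist[i], cand$pair_dist[j])) {
              ok <- FALSE
              break
            }
          }
          if (!ok) break
        }
        accept[i] <- ok
      }
      cand <- cand[accept, , drop = FALSE]
    }

    copy_row <- function(id) copies[match(id, copies$copy_id), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      pair <- cand[i, , drop = FALSE]
      te_identity <- pairwise_identity(
        copies$seq[match(pair$member_a, copies$copy_id)],
        copies$seq[match(pair$member_b, copies$copy_id)], "global")
      ca <- copy_row(pair$member_a); cb <- copy_row(pair$member_b)
      fa <- extract_flanks(ca, genomes[[ca$species]], flank_len)
      fb <- extract_flanks(cb, genomes[[cb$species]], flank_len)
      fl <- flank_contrast_test(fa, fb, te_identity, flank_max, margin)
      rbh_ok <- rbh_confirm(pair, copies, clusters)
      sup <- score_ht_support(members, dmat, pair, species_tree,
                              discordance_margin, pair_dist = pair$pair_dist)

      status <- if (fl$contamination) "likely_contamination"
        else if (!fl$scaffold_ok) "likely_artefact"
        else if (fl$flank_ok && rbh_ok && isTRUE(sup$tree_discordant) &&
                 sup$support_score < support_max) "confirmed"
        else "rejected"

      report[[length(report) + 1L]] <- tibble(
        cluster_id = cid, rank = rank, n_members = length(member_ids),
        member_a = pair$member_a, member_b = pair$member_b,
        species_a = pair$species_a, species_b = pair$species_b,
        rank_a = pair$rank_a, rank_b = pair$rank_b,
        te_identity = te_identity,
        flank_left_identity = fl$left_identity,
        flank_right_identity = fl$right_identity,
        flank_ok = fl$flank_ok, rbh_ok = rbh_ok, scaffold_ok = fl$scaffold_ok,
        tree_discordant = sup$tree_discordant,
        support_score = sup$support_score, status = status)
    }
  }
  assemble_report(report)
}

#' Assemble the HT report table
#'
#' @param candidates list of one-row candidate tibbles (or an existing
#'   report tibble).
#' @return tibble sorted by `support_score` (empty report allowed).
#' @export
assemble_report <- function(candidates) {
  if (is.data.frame(candidates)) {
    rep <- candidates
  } else if (length(candidates) == 0) {
    rep <- tibble(
      cluster_id = character(0), rank = character(0), n_members = integer(0),
      member_a = character(0), member_b = character(0),
      species_a = character(0), species_b = character(0),
      rank_a = character(0), rank_b = character(0), te_identity = numeric(0),
      flank_left_identity = numeric(0), flank_right_identity = numeric(0),
      flank_ok = logical(0), rbh_ok = logical(0), scaffold_ok = logical(0),
      tree_discordant = logical(0), support_score = numeric(0),
      status = character(0))
  } else {
    rep <- do.call(rbind, candidates)
  }
  rep[order(rep$support_score), , drop = FALSE]
}

#' One-line-per-candidate summary of an HT report
#' @param report tibble from [detect_ht()].
#' @return character vector.
#' @export
summarise_ht_report <- function(report) {
  if (nrow(report) == 0) return("no cross-rank candidate clusters")
  vapply(seq_len(nrow(report)), function(i) {
    sprintf("%s: %s (%s) ~ %s (%s), TE identity %.2f, support %.2f -> %s",
            report$cluster_id[i], report$species_a[i], report$rank_a[i],
            report$species_b[i], report$rank_b[i], report$te_identity[i],
            report$support_score[i], report$status[i])
  }, character(1))
}
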