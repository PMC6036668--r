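# Ground-truthed simulator of TE evolution along a species tree: vertical
# descent with K2P substitution accumulation, copy-and-paste amplification of
# active copies, permanent inactivation, planted horizontal transfer events,
# and decay by segmental deletion. Branch lengths are in expected
# substitutions per site; all rates are per unit branch length.

seq_to_int <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], .ht_bases) - 1L
  v[is.na(v)] <- sample.int(4L, sum(is.na(v)), replace = TRUE) - 1L  # N -> random base
  v
}

int_to_seq <- function(v) paste(.ht_bases[v + 1L], collapse = "")

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Apply K2P substitutions to a DNA sequence
#'
#' Substitution events are Poisson with mean `t * length`; each event is a
#' transition with probability `kappa / (kappa + 2)`, otherwise one of the two
#' transversions. Sites are drawn with replacement, so multiple hits occur as
#' in the model the downstream K2P estimator corrects for.
#'
#' @param seq DNA string or integer-encoded vector.
#' @param t branch length (expected substitutions per site).
#' @param kappa transition/transversion rate ratio.
#' @return same type as the input.
#' @export
mutate_seq <- function(seq, t, kappa = 2) {
  was_char <- is.character(seq)
  v <- if (was_char) seq_to_int(seq) else seq
  n <- rpois(1L, t * length(v))
  if (n > 0L) {
    sites <- sample.int(length(v), n, replace = TRUE)
    for (s in sites) {
      cur <- v[s]
      if (runif(1) < kappa / (kappa + 2)) {
        v[s] <- c(2L, 3L, 0L, 1L)[cur + 1L]          # A<->G, C<->T
      } else {
        v[s] <- if (cur %in% c(0L, 2L)) {            # purine -> pyrimidine
          if (runif(1) < 0.5) 1L else 3L
        } else {
          if (runif(1) < 0.5) 0L else 2L
        }
      }
    }
  }
  if (was_char) int_to_seq(v) else v
}

#' Canonical synthetic master TE
#'
#' A deterministic 3.2-kb LINE-like master element: 150-bp 5'UTR, a single
#' 901-codon open reading frame whose translation embeds a 220-aa
#' reverse-transcriptase-like region, and a 3'UTR padding to 3200 bp. The
#' element is synthetic (built from a fixed internal seed), not a RepBase
#' consensus.
#'
#' @return character scalar of length 3200.
#' @export
canonical_te <- function() {
  with_seed(990713L, {
    aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
    codons_by_aa <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
    rt <- rt_consensus_aa()
    prot <- c(sample(aa20, 300, replace = TRUE), strsplit(rt, "")[[1]],
              sample(aa20, 380, replace = TRUE))
    codons <- vapply(prot, function(a) {
      cs <- codons_by_aa[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1))
    orf <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    utr5 <- paste(sample(.ht_bases, 150, replace = TRUE), collapse = "")
    utr3 <- paste(sample(.ht_bases, 3200 - 150 - nchar(orf), replace = TRUE),
                  collapse = "")
    paste0(utr5, orf, utr3)
  })
}

#' Synthetic RT-domain consensus and seed alignment
#'
#' `rt_consensus_aa()` is the fixed 220-aa reverse-transcriptase-like region
#' embedded in [canonical_te()]. `rt_seed_alignment()` derives a gapless seed
#' alignment of diverged variants, the input for [build_pssm()]. Both are
#' synthetic stand-ins for a curated RT seed alignment, generated from fixed
#' internal seeds.
#'
#' @return `rt_consensus_aa`: character scalar (220 aa).
#' @export
rt_consensus_aa <- function() {
  with_seed(411202L, {
    aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
    paste(sample(aa20, 220, replace = TRUE), collapse = "")
  })
}

#' @rdname rt_consensus_aa
#' @param n number of seed sequences.
#' @param divergence per-position substitution probability in each variant.
#' @return `rt_seed_alignment`: named character vector of aligned sequences.
#' @export
rt_seed_alignment <- function(n = 8L, divergence = 0.15) {
  cons <- strsplit(rt_consensus_aa(), "")[[1]]
  aa20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  with_seed(58323L, {
    out <- vapply(seq_len(n), function(i) {
      v <- cons
      hit <- runif(length(v)) < divergence
      v[hit] <- sample(aa20, sum(hit), replace = TRUE)
      paste(v, collapse = "")
    }, character(1))
    names(out) <- paste0("rt_seed_", seq_len(n))
    out
  })
}

#' Generate an ultrametric Yule species tree
#'
#' @param n_taxa number of leaves (>= 2), labelled `sp1..spN`.
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @param height if non-NULL, rescale the tree to this root-to-tip height
#'   (expected substitutions per site).
#' @return [ape::phylo] tree.
#' @export
generate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1L,
                                  height = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tr$tip.label <- paste0("sp", seq_len(n_taxa))
  if (!is.null(height)) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * (height / h)
  }
  tr
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of [evolve()]. Defaults are the
#' package's standard study conditions: a 3.2-kb master element, 100-kb
#' background genomes, and rates giving of order 5 full-length copies per
#' species at a tree height of 0.4 substitutions/site.
#'
#' @param tree [ape::phylo] species tree, branch lengths in expected
#'   substitutions per site.
#' @param master master TE sequence (default [canonical_te()]).
#' @param background_genome_length background genome size in bp.
#' @param n_initial_copies active master copies present at the root.
#' @param amplification_rate expected new copies per active copy per unit
#'   branch length.
#' @param inactivation_prob probability that a newly inserted daughter copy is
#'   dead on arrival (inactivation is permanent).
#' @param kappa K2P transition/transversion rate ratio.
#' @param ht_events NULL, or a data frame with columns `donor`, `recipient`
#'   (tip labels), `time_frac` (position of the transfer along the recipient
#'   branch, in (0,1)), `n_copies` (founder copies seeded).
#' @param seed RNG seed; the whole simulation is bit-reproducible given it.
#' @return validated config list.
#' @export
sim_config <- function(tree, master = canonical_te(),
                       background_genome_length = 100000L,
                       n_initial_copies = 3L, amplification_rate = 2,
                       inactivation_prob = 0.2, kappa = 2,
                       ht_events = NULL, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  stopifnot(amplification_rate >= 0, inactivation_prob >= 0,
            inactivation_prob <= 1, kappa > 0, n_initial_copies >= 1)
  if (!is.null(ht_events)) {
    ht_events <- as.data.frame(ht_events)
    need <- c("donor", "recipient")
    stopifnot(all(need %in% names(ht_events)))
    if (is.null(ht_events$time_frac)) ht_events$time_frac <- 0.9
    if (is.null(ht_events$n_copies)) ht_events$n_copies <- 1L
    stopifnot(all(ht_events$donor != ht_events$recipient),
              all(ht_events$time_frac > 0), all(ht_events$time_frac < 1))
  }
  list(tree = tree, master = master,
       background_genome_length = as.integer(background_genome_length),
       n_initial_copies = as.integer(n_initial_copies),
       amplification_rate = amplification_rate,
       inactivation_prob = inactivation_prob, kappa = kappa,
       ht_events = ht_events, seed = as.integer(seed))
}

#' Evolve TE copies along a species tree
#'
#' Event-driven simulation per branch: active copies replicate at
#' `amplification_rate` (Gillespie birth process), every copy accumulates K2P
#' substitutions continuously, planted HT events snapshot a random active
#' donor-lineage copy at the event time and seed founder copies into the
#' recipient branch. At the leaves, copies are placed on random non-adjacent
#' intervals (spacing > 1200 bp, so 1-kb flanks never cross a neighbouring
#' copy) of an i.i.d.-uniform background genome, on a random strand.
#'
#' @param config list from [sim_config()].
#' @return list with `genomes` (named species -> scaffold string), `truth`
#'   (tibble: `copy_id`, `species`, `scaffold`, `start`, `end`, `strand`,
#'   `birth_time`, `age`, `parent_copy_id`, `horizontal`, `active`, `intact`,
#'   `seq`), `tree`, `master`, `config`.
#' @export
evolve <- function(config) {
  set.seed(config$seed)
  tree <- config$tree
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  edges <- tree$edge
  elen <- tree$edge.length
  nedge <- nrow(edges)
  root <- ntip + 1L

  # resolve HT events to edges and absolute times
  snaps_by_edge <- vector("list", nedge)   # snapshot requests (donor side)
  injs_by_edge <- vector("list", nedge)    # injections (recipient side)
  deps <- matrix(integer(0), ncol = 2)     # donor edge must precede recipient
  ht <- config$ht_events
  if (!is.null(ht) && nrow(ht) > 0) {
    node_of <- function(lab) {
      i <- match(lab, tree$tip.label)
      if (is.na(i)) stop("unknown tip in ht_events: ", lab)
      i
    }
    for (k in seq_len(nrow(ht))) {
      dn <- node_of(ht$donor[k]); rn <- node_of(ht$recipient[k])
      de <- which(edges[, 2] == dn); re <- which(edges[, 2] == rn)
      t_ev <- depth[edges[re, 1]] + ht$time_frac[k] * elen[re]
      if (t_ev < depth[edges[de, 1]] || t_ev > depth[dn]) {
        stop("HT event ", k, ": time ", signif(t_ev, 4),
             " falls outside the donor branch of ", ht$donor[k])
      }
      snaps_by_edge[[de]] <- rbind(snaps_by_edge[[de]],
                                   data.frame(event = k, t = t_ev))
      injs_by_edge[[re]] <- rbind(injs_by_edge[[re]],
                                  data.frame(event = k, t = t_ev,
                                             n = ht$n_copies[k]))
      deps <- rbind(deps, c(de, re))
    }
  }

  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("cp%05d", counter)
  }
  advance <- function(cp, t) {
    dt <- t - cp$last
    if (dt > 0) {
      cp$seq <- mutate_seq(cp$seq, dt, config$kappa)
      cp$last <- t
    }
    cp
  }

  master_int <- seq_to_int(config$master)
  root_state <- lapply(seq_len(config$n_initial_copies), function(i) {
    list(id = new_id(), seq = master_int, active = TRUE, birth = 0,
         parent = NA_character_, horizontal = FALSE, last = 0)
  })

  snapshots <- vector("list", if (is.null(ht)) 0L else nrow(ht))
  simulate_edge <- function(state, t0, t1, snaps, injs) {
    sched <- rbind(
      if (!is.null(snaps)) data.frame(t = snaps$t, kind = "snap", event = snaps$event, n = 0L),
      if (!is.null(injs)) data.frame(t = injs$t, kind = "inj", event = injs$event, n = injs$n))
    if (!is.null(sched)) sched <- sched[order(sched$t), , drop = FALSE]
    si <- 1L
    t <- t0
    repeat {
      n_active <- sum(vapply(state, `[[`, TRUE, "active"))
      t_birth <- if (config$amplification_rate > 0 && n_active > 0) {
        t + rexp(1, config$amplification_rate * n_active)
      } else Inf
      t_sched <- if (!is.null(sched) && si <= nrow(sched)) sched$t[si] else Inf
      if (min(t_birth, t_sched) >= t1) {
        state <- lapply(state, advance, t = t1)
        break
      }
      if (t_birth < t_sched) {
        t <- t_birth
        act <- which(vapply(state, `[[`, TRUE, "active"))
        p <- act[sample.int(length(act), 1L)]
        state[[p]] <- advance(state[[p]], t)
        state[[length(state) + 1L]] <- list(
          id = new_id(), seq = state[[p]]$seq,
          active = runif(1) >= config$inactivation_prob,
          birth = t, parent = state[[p]]$id,
          horizontal = state[[p]]$horizontal, last = t)
      } else {
        t <- t_sched
        row <- sched[si, ]
        si <- si + 1L
        if (row$kind == "snap") {
          act <- which(vapply(state, `[[`, TRUE, "active"))
          if (length(act) == 0) stop("HT event ", row$event,
                                     ": donor lineage has no active copies")
          p <- act[sample.int(length(act), 1L)]
          state[[p]] <- advance(state[[p]], t)
          snapshots[[row$event]] <<- list(seq = state[[p]]$seq,
                                          donor_id = state[[p]]$id)
        } else {
          snap <- snapshots[[row$event]]
          if (is.null(snap)) stop("HT event ", row$event,
                                  ": injection before donor snapshot")
          for (i in seq_len(row$n)) {
            state[[length(state) + 1L]] <- list(
              id = new_id(), seq = snap$seq, active = TRUE, birth = t,
              parent = snap$donor_id, horizontal = TRUE, last = t)
          }
        }
      }
    }
    state
  }

  # order edges: parents first, donor edges before recipient edges
  parent_edge <- match(edges[, 1], edges[, 2])       # NA for root children
  done <- rep(FALSE, nedge)
  order_out <- integer(0)
  while (length(order_out) < nedge) {
    ready <- which(!done &
      (is.na(parent_edge) | done[pmax(parent_edge, 1L)] | is.na(parent_edge)))
    ready <- ready[vapply(ready, function(e) {
      pe <- parent_edge[e]
      ok <- is.na(pe) || done[pe]
      if (ok && nrow(deps) > 0) {
        need <- deps[deps[, 2] == e, 1]
        ok <- all(done[need])
      }
      ok
    }, TRUE)]
    if (length(ready) == 0) stop("cyclic HT dependencies between branches")
    # deterministic order: by depth of parent node, then edge index
    ready <- ready[order(depth[edges[ready, 1]], ready)]
    e <- ready[1]
    order_out <- c(order_out, e)
    done[e] <- TRUE
  }

  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- root_state
  for (e in order_out) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    states[[ch]] <- simulate_edge(states[[p]], depth[p], depth[ch],
                                  snaps_by_edge[[e]], injs_by_edge[[e]])
  }

  # place copies into background genomes
  G <- config$background_genome_length
  genomes <- character(0)
  rows <- list()
  min_spacing <- 1200L
  for (i in seq_len(ntip)) {
    sp <- tree$tip.label[i]
    copies <- states[[i]]
    lens <- vapply(copies, function(c) length(c$seq), 1L)
    if (sum(lens + min_spacing) > 0.6 * G) {
      stop("genome too small for ", length(copies), " copies in ", sp)
    }
    gv <- sample.int(4L, G, replace = TRUE) - 1L
    placed <- matrix(numeric(0), ncol = 2)
    for (k in seq_along(copies)) {
      len <- lens[k]
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(G - len + 1L, 1L) - 1L
        if (nrow(placed) == 0 ||
            all(s >= placed[, 2] + min_spacing | s + len <= placed[, 1] - min_spacing)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place copy in ", sp, " (genome too crowded)")
      placed <- rbind(placed, c(s, s + len))
      strand <- if (runif(1) < 0.5) "+" else "-"
      el <- int_to_seq(copies[[k]]$seq)
      ins <- if (strand == "-") seq_to_int(revcomp(el)) else copies[[k]]$seq
      gv[(s + 1L):(s + len)] <- ins
      rows[[length(rows) + 1L]] <- tibble(
        copy_id = paste0(sp, "_", copies[[k]]$id), species = sp,
        scaffold = "scf1", start = s, end = s + len, strand = strand,
        birth_time = copies[[k]]$birth, age = depth[i] - copies[[k]]$birth,
        parent_copy_id = copies[[k]]$parent,
        horizontal = copies[[k]]$horizontal, active = copies[[k]]$active,
        intact = TRUE, seq = el)
    }
    genomes[sp] <- int_to_seq(gv)
  }
  truth <- do.call(rbind, rows)
  list(genomes = genomes, truth = truth, tree = tree,
       master = config$master, config = config)
}

#' Fragment simulated TE copies by segmental deletion
#'
#' Each copy suffers `Poisson(deletion_rate * age)` deletion events. Deletion
#' sizes are uniform on `deletion_size_range` (31 bp to 10 kb); the deleted
#' span is clipped to the copy so neighbouring sequence is untouched. Copies
#' whose remaining length falls below `min_intact_length` are marked
#' non-intact; fully deleted copies are dropped from the truth table.
#'
#' @param sim result of [evolve()].
#' @param deletion_rate deletion events per copy per unit branch length of
#'   copy age.
#' @param deletion_size_range integer range of deletion sizes in bp.
#' @param min_intact_length intactness threshold on remaining length (the
#'   2-kb cut-off used for representative selection).
#' @param seed optional RNG seed.
#' @return `sim` with updated `genomes` and `truth`.
#' @export
fragment <- function(sim, deletion_rate, deletion_size_range = c(31L, 10000L),
                     min_intact_length = 2000L, seed = NULL) {
  if (deletion_rate == 0) return(sim)
  if (!is.null(seed)) set.seed(seed)
  truth <- sim$truth
  genomes <- sim$genomes
  for (sp in names(genomes)) {
    rows <- which(truth$species == sp)
    G <- nchar(genomes[[sp]])
    keep <- rep(TRUE, G)
    for (r in rows) {
      len <- truth$end[r] - truth$start[r]
      nd <- rpois(1L, deletion_rate * truth$age[r])
      if (nd == 0) next
      for (d in seq_len(nd)) {
        size <- sample(deletion_size_range[1]:deletion_size_range[2], 1L)
        off <- sample((-(size - 1L)):(len - 1L), 1L)
        rel <- c(max(off, 0L), min(off + size, len))
        if (rel[2] <= rel[1]) next
        span <- truth$start[r] + rel
        keep[(span[1] + 1L):span[2]] <- FALSE
      }
    }
    if (all(keep)) next
    shift <- c(0L, cumsum(keep))          # kept positions strictly before x
    gs <- strsplit(genomes[[sp]], "", fixed = TRUE)[[1]]
    genomes[[sp]] <- paste(gs[keep], collapse = "")
    for (r in rows) {
      ns <- shift[truth$start[r] + 1L]
      ne <- shift[truth$end[r] + 1L]
      truth$start[r] <- ns
      truth$end[r] <- ne
      truth$intact[r] <- (ne - ns) >= min_intact_length
      if (ne > ns) {
        truth$seq[r] <- extract_interval(genomes[[sp]], ns, ne, truth$strand[r])
      }
    }
  }
  empty <- truth$end <= truth$start
  truth <- truth[!empty, , drop = FALSE]
  sim$genomes <- genomes
  sim$truth <- truth
  sim
}

#' Split a tree's species into two taxonomic classes at the root
#'
#' Taxonomy for simulated species: the two clades descending from the root
#' become `class_A` / `class_B` (and matching `phylum_A` / `phylum_B`);
#' order is one per species. Synthetic labels, used by the cross-rank filter.
#'
#' @param tree [ape::phylo] tree.
#' @return taxonomy tibble (`species`, `phylum`, `class`, `order`).
#' @export
assign_taxonomy <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  in_a <- rep(FALSE, ntip)
  first <- kids[1]
  if (first <= ntip) {
    in_a[first] <- TRUE
  } else {
    desc <- ape::extract.clade(tree, first)$tip.label
    in_a[match(desc, tree$tip.label)] <- TRUE
  }
  tibble(species = tree$tip.label,
         phylum = ifelse(in_a, "phylum_A", "phylum_B"),
         class = ifelse(in_a, "class_A", "class_B"),
         order = paste0("order_", tree$tip.label))
}

#' Plant cross-class HT events on a simulated tree
#'
#' Chooses donor species from one class and recipients from the other
#' (deterministically, by tip label order), placing each transfer at
#' `time_frac` along the recipient's terminal branch. Donors whose terminal
#' branch does not span the event time are skipped.
#'
#' @param tree [ape::phylo] tree.
#' @param taxonomy tibble from [assign_taxonomy()].
#' @param n_events number of transfer events.
#' @param time_frac event position along the recipient branch.
#' @param n_copies founder copies per event.
#' @return data frame suitable for `sim_config(ht_events = )`.
#' @export
ht_scenario <- function(tree, taxonomy, n_events = 2L, time_frac = 0.9,
                        n_copies = 2L) {
  depth <- ape::node.depth.edgelength(tree)
  branch_start <- function(tip) {
    e <- which(tree$edge[, 2] == match(tip, tree$tip.label))
    depth[tree$edge[e, 1]]
  }
  a <- sort(taxonomy$species[taxonomy$class == "class_A"])
  b <- sort(taxonomy$species[taxonomy$class == "class_B"])
  smaller <- if (length(a) <= length(b)) a else b
  larger <- if (length(a) <= length(b)) b else a
  # recipients come from the rarer lineage (a transfer into a sparsely
  # colonised clade is the clearest pattern), donors from the other class;
  # the two sets stay disjoint so transfer histories never interleave on a
  # branch. Recipients are reused only once the rarer class is exhausted;
  # donors are kept distinct across events.
  recipient_order <- rep_len(smaller, n_events)
  used_donors <- character(0)
  ev <- list()
  for (k in seq_len(n_events)) {
    recip <- recipient_order[k]
    pool <- c(setdiff(larger, used_donors), intersect(larger, used_donors))
    done <- FALSE
    for (tf in seq(time_frac, 0.1, by = -0.1)) {
      t_ev <- branch_start(recip) +
        tf * (depth[match(recip, tree$tip.label)] - branch_start(recip))
      for (cand in pool) {
        if (branch_start(cand) <= t_ev) {
          ev[[k]] <- data.frame(donor = cand, recipient = recip,
                                time_frac = tf, n_copies = n_copies)
          used_donors <- c(used_donors, cand)
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) stop("no feasible donor for HT event ", k)
  }
  do.call(rbind, ev)
}

#' Write a simulation to disk
#'
#' Emits one genome FASTA per species, `truth.tsv`, `species_tree.nwk`,
#' `master.fa`, `taxonomy.tsv` (if given) and a provenance log with the seed.
#'
#' @param sim result of [evolve()] / [fragment()].
#' @param dir output directory (created).
#' @param taxonomy optional taxonomy tibble.
#' @export
write_simulation <- function(sim, dir, taxonomy = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(sim$genomes)) {
    write_fasta(setNames(sim$genomes[sp], "scf1"), file.path(dir, paste0(sp, ".fa")))
  }
  write_copy_table(sim$truth, file.path(dir, "truth.tsv"))
  write_newick(sim$tree, file.path(dir, "species_tree.nwk"))
  write_fasta(c(master = sim$master), file.path(dir, "master.fa"))
  if (!is.null(taxonomy)) write_taxonomy(taxonomy, file.path(dir, "taxonomy.tsv"))
  writeLines(c(paste("seed:", sim$config$seed),
               paste("species:", length(sim$genomes)),
               paste("copies:", nrow(sim$truth)),
               paste("amplification_rate:", sim$config$amplification_rate),
               paste("inactivation_prob:", sim$config$inactivation_prob),
               paste("kappa:", sim$config$kappa)),
             file.path(dir, "provenance.log"))
  invisible(dir)
}
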