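# Pipeline orchestration: a validated configuration drives
# simulate -> mine -> features -> cluster -> detect -> divergence, with every
# stage's outputs written before the next stage reads them, and a provenance
# log. Reruns with the same config are bit-identical.

#' Default pipeline configuration
#'
#' The package's standard study conditions: 12 species on an ultrametric Yule
#' tree of height 0.4 substitutions/site split into two classes at the root,
#' a 3.2-kb master element, 200-kb background genomes, amplification rate 2
#' per active copy per unit branch length, 20% dead-on-arrival insertions,
#' decay by 31 bp - 10 kb segmental deletions, and (optionally) two planted
#' cross-class transfer events late on recipient branches.
#'
#' @param seed integer seed driving every stage.
#' @param n_ht_events number of planted cross-class HT events.
#' @return nested config list (see [validate_config()]).
#' @export
default_config <- function(seed = 1L, n_ht_events = 2L) {
  list(
    seed = as.integer(seed),
    sim = list(n_taxa = 12L, tree_height = 0.4, birth_rate = 1,
               background_genome_length = 200000L, n_initial_copies = 3L,
               amplification_rate = 2, inactivation_prob = 0.2, kappa = 2,
               deletion_rate = 0.15, n_ht_events = as.integer(n_ht_events),
               ht_time_frac = 0.9, ht_n_copies = 2L),
    mine = list(word_size = 11L, x_drop = 50, min_identity = 0.5,
                min_length = 100L, max_gap = 500L, rbh_min_identity = 0.6),
    features = list(consensus_identity = 0.8, centroid_min = 2000L,
                    centroid_max = 4000L, min_orf_aa = 200L),
    cluster = list(engine = "greedy", threshold = 0.55, kind = "nt"),
    detect = list(rank = "class", flank_len = 1000L, flank_max = 0.6,
                  margin = 0.1, support_max = 1, discordance_margin = 0.75),
    divergence = list(bin_width = 1))
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a config list or a YAML file path. Unknown keys are rejected;
#' ranges are checked; missing keys are filled from [default_config()].
#'
#' @param config list or YAML path.
#' @return normalised config list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (blk in intersect(names(config), c("sim", "mine", "features", "cluster",
                                         "detect", "divergence"))) {
    bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(bad) > 0) {
      stop("unknown keys in '", blk, "': ", paste(bad, collapse = ", "))
    }
    def[[blk]] <- modifyList(def[[blk]], config[[blk]])
  }
  if (!is.null(config$seed)) def$seed <- as.integer(config$seed)
  with(def$cluster, {
    if (threshold <= 0 || threshold > 1) stop("cluster threshold out of (0, 1]")
    if (!engine %in% c("greedy", "single")) stop("unknown cluster engine: ", engine)
  })
  if (!def$detect$rank %in% c("class", "phylum")) {
    stop("detect rank must be class or phylum")
  }
  with(def$sim, {
    if (amplification_rate < 0 || deletion_rate < 0) stop("rates must be >= 0")
    if (inactivation_prob < 0 || inactivation_prob > 1) {
      stop("inactivation_prob out of [0, 1]")
    }
    if (n_taxa < 2) stop("n_taxa must be >= 2")
  })
  def
}

#' Simulate the study dataset for a configuration
#'
#' @param config normalised config.
#' @return list: `sim` (see [evolve()]), `taxonomy`, `ht_events`.
#' @export
simulate_stage <- function(config) {
  s <- config$sim
  tree <- generate_species_tree(s$n_taxa, s$birth_rate, seed = config$seed,
                                height = s$tree_height)
  taxonomy <- assign_taxonomy(tree)
  ht <- if (s$n_ht_events > 0) {
    ht_scenario(tree, taxonomy, s$n_ht_events, s$ht_time_frac, s$ht_n_copies)
  }
  cfg <- sim_config(tree, background_genome_length = s$background_genome_length,
                    n_initial_copies = s$n_initial_copies,
                    amplification_rate = s$amplification_rate,
                    inactivation_prob = s$inactivation_prob, kappa = s$kappa,
                    ht_events = ht, seed = config$seed)
  sim <- evolve(cfg)
  sim <- fragment(sim, s$deletion_rate, seed = config$seed + 1L)
  list(sim = sim, taxonomy = taxonomy, ht_events = ht)
}

#' Mine all simulated genomes against the family library
#'
#' @param genomes named character vector (species -> scaffold).
#' @param repeat_library tibble (`id`, `family`, `seq`).
#' @param params mining parameter block.
#' @return combined copies tibble.
#' @export
mine_stage <- function(genomes, repeat_library, params = list()) {
  out <- lapply(names(genomes), function(sp) {
    mine_genome(genomes[[sp]], repeat_library, species = sp, params = params)
  })
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Runs the requested stages in order, writing each stage's outputs under
#' `out_dir` before the next stage reads its inputs, and a provenance log
#' (seed, config checksum). Any stage failure aborts with the stage name.
#'
#' @param config config list or YAML path (validated first).
#' @param out_dir run directory (created).
#' @param stages subset of
#'   `c("simulate","mine","features","cluster","detect","divergence")`;
#'   stages are always executed in pipeline order.
#' @return (invisibly) list with `sim`, `taxonomy`, `copies`,
#'   `representatives`, `clusters`, `report`, `landscape`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "mine", "features", "cluster",
                                    "detect", "divergence")) {
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(out_dir = out_dir)
  log <- file.path(out_dir, "log.txt")
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  note <- function(...) cat(..., "\n", sep = "", file = log, append = TRUE)
  cat("", file = log)
  note("htscan run, seed ", config$seed)
  note("config md5 ", unname(tools::md5sum(cfg_path)))

  run <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("simulate" %in% stages) {
    run("simulate", function() {
      st <- simulate_stage(config)
      res$sim <<- st$sim
      res$taxonomy <<- st$taxonomy
      res$ht_events <<- st$ht_events
      write_simulation(st$sim, file.path(out_dir, "sim"), st$taxonomy)
      note("simulate: ", length(st$sim$genomes), " genomes, ",
           nrow(st$sim$truth), " true copies, ",
           sum(st$sim$truth$horizontal), " horizontal")
    })
  }
  library_tbl <- tibble(id = "BovB_master", family = "BovB",
                        seq = if (!is.null(res$sim)) res$sim$master else canonical_te())

  if ("mine" %in% stages) {
    run("mine", function() {
      copies <- mine_stage(res$sim$genomes, library_tbl, config$mine)
      res$copies <<- copies
      dir.create(file.path(out_dir, "mine"), showWarnings = FALSE)
      write_copy_table(res$copies, file.path(out_dir, "mine", "copies.tsv"))
      write_fasta(tibble(id = copies$copy_id,
                         desc = copy_desc(copies$species, copies$scaffold,
                                          copies$start, copies$end,
                                          copies$strand),
                         seq = copies$seq),
                  file.path(out_dir, "mine", "copies.fa"))
      note("mine: ", nrow(copies), " copies")
    })
  }

  if ("features" %in% stages) {
    run("features", function() {
      res$copies <<- annotate_intact(res$copies, config$features$min_orf_aa)
      note("features: ", sum(res$copies$intact), " intact copies")
      reps <- list()
      for (sp in unique(res$copies$species)) {
        cp <- res$copies[res$copies$species == sp, , drop = FALSE]
        cen <- select_centroid(cp, config$features$centroid_min,
                               config$features$centroid_max)
        if (!is.null(cen)) {
          cen$species <- sp
          reps[[length(reps) + 1L]] <- cen
        } else {
          con <- build_consensus(cp, config$features$consensus_identity)
          if (nrow(con) > 0) {
            con <- con[which.max(con$n_supporting_copies), , drop = FALSE]
            con$species <- sp
            reps[[length(reps) + 1L]] <- con[, c("rep_id", "method", "seq",
                                                 "n_supporting_copies",
                                                 "species")]
          }
        }
      }
      reps <- if (length(reps) > 0) do.call(rbind, reps) else NULL
      res$representatives <<- reps
      dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
      if (!is.null(reps)) {
        write_fasta(tibble(id = paste0(reps$species, "_", reps$method),
                           desc = reps$rep_id, seq = reps$seq),
                    file.path(out_dir, "features", "representatives.fa"))
      }
      note("features: ", if (is.null(reps)) 0 else nrow(reps),
           " species representatives")
    })
  }

  if ("cluster" %in% stages) {
    run("cluster", function() {
      full <- filter_full_length(res$copies)
      seqs <- setNames(full$seq, full$copy_id)
      cl <- if (config$cluster$engine == "greedy") {
        greedy_centroid_cluster(seqs, config$cluster$threshold,
                                kind = config$cluster$kind)
      } else {
        single_linkage_cluster(seqs, config$cluster$threshold,
                               kind = config$cluster$kind)
      }
      res$clusters <<- cl
      dir.create(file.path(out_dir, "cluster"), showWarnings = FALSE)
      write_cluster_table(cl, file.path(out_dir, "cluster", "clusters.tsv"),
                          res$copies, res$taxonomy)
      note("cluster: ", length(unique(cl$cluster_id)), " clusters over ",
           nrow(cl), " full-length copies at identity ",
           config$cluster$threshold)
    })
  }

  if ("detect" %in% stages) {
    run("detect", function() {
      rep <- detect_ht(res$clusters, res$copies, res$sim$genomes,
                       res$taxonomy, res$sim$tree,
                       rank = config$detect$rank,
                       flank_len = config$detect$flank_len,
                       flank_max = config$detect$flank_max,
                       margin = config$detect$margin,
                       support_max = config$detect$support_max,
                       discordance_margin = config$detect$discordance_margin)
      res$report <<- rep
      dir.create(file.path(out_dir, "detect"), showWarnings = FALSE)
      write.table(rep, file.path(out_dir, "detect", "ht_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(summarise_ht_report(rep),
                 file.path(out_dir, "detect", "ht_summary.txt"))
      note("detect: ", nrow(rep), " cross-", config$detect$rank,
           " candidates, ", sum(rep$status == "confirmed"), " confirmed")
    })
  }

  if ("divergence" %in% stages) {
    run("divergence", function() {
      rows <- list()
      for (sp in unique(res$copies$species)) {
        cp <- res$copies[res$copies$species == sp, , drop = FALSE]
        ls <- divergence_landscape(cp, library_tbl$seq[1],
                                   config$divergence$bin_width)
        if (nrow(ls$profile) > 0) {
          prof <- ls$profile
          prof$species <- sp
          rows[[sp]] <- prof
        }
      }
      land <- if (length(rows) > 0) do.call(rbind, rows) else NULL
      res$landscape <<- land
      dir.create(file.path(out_dir, "divergence"), showWarnings = FALSE)
      if (!is.null(land)) {
        write.table(land, file.path(out_dir, "divergence", "landscape.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      note("divergence: landscapes for ",
           if (is.null(land)) 0 else length(unique(land$species)), " species")
    })
  }
  invisible(res)
}
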