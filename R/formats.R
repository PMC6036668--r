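# FASTA / Newick / TSV plumbing. Conventions used everywhere:
#  * coordinates 0-based half-open, BED-style TSV export;
#  * DNA uppercased on read, U -> T, ambiguity codes other than N -> N;
#  * mined-copy FASTA descriptions carry "species|scaffold|start|end|strand".

#' Read a FASTA file
#'
#' Wrapped or single-line FASTA. Sequences are uppercased; in DNA mode `U` is
#' mapped to `T` and ambiguity codes other than `N` are mapped to `N`.
#' Duplicate ids and empty sequences are errors.
#'
#' @param path file path.
#' @param mode `"dna"` or `"protein"`.
#' @return tibble with columns `id`, `desc`, `seq` (input order preserved).
#' @export
read_fasta <- function(path, mode = c("dna", "protein")) {
  mode <- match.arg(mode)
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- toupper(as.character(set))
  if (any(nchar(seq) == 0L)) {
    stop("empty sequence for id: ", paste(id[nchar(seq) == 0L], collapse = ", "))
  }
  if (mode == "dna") {
    seq <- chartr("U", "T", seq)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  tibble(id = id, desc = unname(desc), seq = unname(seq))
}

#' Write sequences to FASTA
#'
#' @param x tibble with `id`, `seq` and optionally `desc`, or a named
#'   character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    x <- tibble(id = names(x), desc = "", seq = unname(x))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[i])) paste(x$id[i], desc[i]) else x$id[i]
    cat(">", hdr, "\n", sep = "", file = con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Format / parse mined-copy FASTA descriptions
#'
#' Mined copies carry their provenance as `species|scaffold|start|end|strand`
#' in the FASTA description; the parser tolerates plain headers.
#' @param species,scaffold,start,end,strand copy metadata vectors.
#' @return `copy_desc`: character vector of descriptions.
#' @export
copy_desc <- function(species, scaffold, start, end, strand) {
  paste(species, scaffold, start, end, strand, sep = "|")
}

#' @rdname copy_desc
#' @param desc description strings.
#' @return `parse_copy_desc`: tibble with the five fields (NA rows for plain
#'   headers).
#' @export
parse_copy_desc <- function(desc) {
  parts <- strsplit(desc, "|", fixed = TRUE)
  bad <- lengths(parts) != 5L
  parts[bad] <- list(rep(NA_character_, 5L))
  m <- do.call(rbind, parts)
  tibble(species = m[, 1], scaffold = m[, 2],
         start = suppressWarnings(as.integer(m[, 3])),
         end = suppressWarnings(as.integer(m[, 4])),
         strand = m[, 5])
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with the
#' error checks the pipeline relies on. Round-trips preserve topology and
#' branch lengths to at least 1e-9.
#'
#' @param path file path.
#' @return `read_newick`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick in ", path)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a species taxonomy table
#'
#' TSV with columns `species`, `phylum`, `class`, `order` (header required).
#'
#' @param path file path.
#' @return tibble.
#' @export
read_taxonomy <- function(path) {
  tx <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("species", "phylum", "class", "order")
  if (!all(need %in% names(tx))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  }
  tx
}

#' @rdname read_taxonomy
#' @param taxonomy taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster table
#'
#' TSV with one row per member: `cluster_id`, `member_id`, `species`, `class`,
#' `phylum`, `length`, `identity_to_centroid`. Cluster ids carry the kind
#' prefix (`c_` nucleotide, `o_` nucleotide ORF, `r_` amino-acid RT).
#'
#' @param clusters long cluster tibble from a clustering engine
#'   (`cluster_id`, `member_id`, `identity`, ...).
#' @param path output path.
#' @param copies optional copies tibble (`copy_id`, `species`, `seq`) used to
#'   fill species/length columns.
#' @param taxonomy optional taxonomy tibble for class/phylum columns.
#' @export
write_cluster_table <- function(clusters, path, copies = NULL, taxonomy = NULL) {
  out <- tibble(
    cluster_id = character(), member_id = character(), species = character(),
    class = character(), phylum = character(), length = integer(),
    identity_to_centroid = numeric())
  if (!is.null(clusters) && nrow(clusters) > 0) {
    species <- rep(NA_character_, nrow(clusters))
    len <- rep(NA_integer_, nrow(clusters))
    if (!is.null(copies)) {
      i <- match(clusters$member_id, copies$copy_id)
      species <- copies$species[i]
      len <- nchar(copies$seq)[i]
    }
    cls <- phl <- rep(NA_character_, nrow(clusters))
    if (!is.null(taxonomy)) {
      i <- match(species, taxonomy$species)
      cls <- taxonomy$class[i]
      phl <- taxonomy$phylum[i]
    }
    out <- tibble(
      cluster_id = clusters$cluster_id, member_id = clusters$member_id,
      species = species, class = cls, phylum = phl, length = len,
      identity_to_centroid = if ("identity" %in% names(clusters))
        clusters$identity else NA_real_)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a mined-copy table (BED-like TSV)
#'
#' @param copies copies tibble.
#' @param path file path.
#' @export
write_copy_table <- function(copies, path) {
  write.table(copies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_copy_table
#' @export
read_copy_table <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
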