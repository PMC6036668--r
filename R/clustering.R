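# All-against-all clustering by two engines: greedy centroid (VSEARCH-like
# cluster_fast behaviour: length-descending input order, first centroid above
# threshold wins) and single linkage over pairwise hits (BLAST+SiLiX-like:
# any above-threshold connection with sufficient overlap joins families).

cluster_prefix <- function(kind) {
  switch(kind, nt = "c", orf = "o", rt = "r",
         stop("kind must be one of nt, orf, rt"))
}

#' Greedy centroid clustering
#'
#' Sequences are processed in length-descending order (ties by id); each is
#' assigned to the first existing centroid with identity >= `threshold`,
#' otherwise it becomes a new centroid. Deterministic given the input.
#'
#' @param seqs named character vector.
#' @param threshold identity threshold in `(0, 1]` (the analysis uses
#'   0.5-0.6 for ancient-transfer sensitivity).
#' @param kind sequence kind for the cluster-id prefix: `"nt"` (`c_`),
#'   `"orf"` (`o_`), `"rt"` (`r_`).
#' @param mode identity mode passed to [pairwise_identity()].
#' @param prefilter_k if non-NULL, skip the alignment when two sequences
#'   share no k-mer of this size (speed-up only; must not change results on
#'   realistic inputs, and is off by default).
#' @return long tibble: `cluster_id`, `centroid_id`, `member_id`,
#'   `identity`, `threshold`.
#' @export
greedy_centroid_cluster <- function(seqs, threshold, kind = "nt",
                                    mode = "global", prefilter_k = NULL) {
  stopifnot(threshold > 0, threshold <= 1, length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  pre <- cluster_prefix(kind)
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- character(0)          # ids
  assign_rows <- list()
  ksets <- if (!is.null(prefilter_k)) {
    lapply(seqs, function(s) unique(substring(s, 1:(nchar(s) - prefilter_k + 1L),
                                              prefilter_k:nchar(s))))
  }
  for (i in ord) {
    id <- names(seqs)[i]
    hit <- NA_integer_
    hit_ident <- NA_real_
    for (ci in seq_along(centroids)) {
      if (!is.null(prefilter_k) &&
          length(intersect(ksets[[id]], ksets[[centroids[ci]]])) == 0) next
      ident <- pairwise_identity(seqs[[i]], seqs[[centroids[ci]]], mode)
      if (ident >= threshold) { hit <- ci; hit_ident <- ident; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      assign_rows[[id]] <- c(length(centroids), 1.0)
    } else {
      assign_rows[[id]] <- c(hit, hit_ident)
    }
  }
  m <- do.call(rbind, assign_rows)
  tibble(cluster_id = sprintf("%s_%d", pre, m[, 1]),
         centroid_id = centroids[m[, 1]],
         member_id = rownames(m),
         identity = m[, 2],
         threshold = threshold)
}

#' Single-linkage clustering over pairwise hits
#'
#' Nodes are sequences; an edge joins two sequences when a pairwise (local)
#' alignment reaches `threshold` identity over at least
#' `min_overlap_fraction` of the shorter sequence. Clusters are the connected
#' components (union-find), so chains of similarity merge families — the
#' behaviour that groups degraded elements together.
#'
#' @inheritParams greedy_centroid_cluster
#' @param min_overlap_fraction minimum aligned fraction of the shorter
#'   sequence for an edge.
#' @return long tibble: `cluster_id`, `centroid_id` (NA), `member_id`,
#'   `identity` (NA), `threshold`.
#' @export
single_linkage_cluster <- function(seqs, threshold, min_overlap_fraction = 0.5,
                                   kind = "nt", prefilter_k = NULL) {
  stopifnot(threshold > 0, threshold <= 1, length(seqs) > 0)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  ksets <- if (!is.null(prefilter_k)) {
    lapply(seqs, function(s) unique(substring(s, 1:(nchar(s) - prefilter_k + 1L),
                                              prefilter_k:nchar(s))))
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (find(i) == find(j)) next
        if (!is.null(prefilter_k) &&
            length(intersect(ksets[[i]], ksets[[j]])) == 0) next
        al <- align_pair(seqs[[i]], seqs[[j]], mode = "local")
        shorter <- min(nchar(seqs[[i]]), nchar(seqs[[j]]))
        if (al$columns >= min_overlap_fraction * shorter &&
            al$identity >= threshold) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  comp_ids <- match(comp, unique(comp))   # stable numbering by first appearance
  pre <- cluster_prefix(kind)
  tibble(cluster_id = sprintf("%s_%d", pre, comp_ids),
         centroid_id = NA_character_,
         member_id = names(seqs),
         identity = NA_real_,
         threshold = threshold)
}

#' Sweep clustering thresholds
#'
#' Clusters the same input at each threshold and tabulates cluster counts —
#' the tool used to find, e.g., the highest identity at which exactly two
#' families remain.
#'
#' @param seqs named character vector.
#' @param thresholds ascending identity thresholds.
#' @param engine `"greedy"` or `"single"`.
#' @param ... passed to the engine.
#' @return tibble: `threshold`, `n_clusters`, `n_singletons`.
#' @export
threshold_sweep <- function(seqs, thresholds, engine = c("greedy", "single"), ...) {
  engine <- match.arg(engine)
  stopifnot(!is.unsorted(thresholds))
  rows <- lapply(thresholds, function(th) {
    cl <- if (engine == "greedy") greedy_centroid_cluster(seqs, th, ...)
          else single_linkage_cluster(seqs, th, ...)
    sizes <- table(cl$cluster_id)
    tibble(threshold = th, n_clusters = length(sizes),
           n_singletons = sum(sizes == 1))
  })
  do.call(rbind, rows)
}
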