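#' Build a sequence similarity network
#'
#' All-vs-all local alignment ([local_align_evalue()]); an edge joins two
#' sequences when the alignment score `-log10(E)` reaches the threshold.
#' The alignment-score thresholds used for the published RRE networks are
#' 22 and 25 (E-value cutoffs of 1e-22 and 1e-25).
#'
#' @param proteins Protein tibble (`id`, `sequence`), >= 2 rows.
#' @param alignment_score_threshold Minimum `-log10(E)` for an edge.
#' @param n_db Database-size multiplier for the E-values; defaults to the
#'   number of input sequences.
#' @return Object of class `rre_ssn`: an igraph graph plus the edge
#'   table, the construction threshold and (after
#'   [conflate_repnodes()]) the representative-node map.
#' @export
build_ssn <- function(proteins, alignment_score_threshold = 22,
                      n_db = nrow(proteins)) {
  stopifnot(nrow(proteins) >= 2)
  ids <- proteins$id
  stopifnot(!anyDuplicated(ids))
  pairs <- utils::combn(nrow(proteins), 2)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ev <- local_align_evalue(proteins$sequence[[i]], proteins$sequence[[j]],
                             n_db = n_db)
    score <- -log10(ev$evalue)
    tibble::tibble(id_a = ids[i], id_b = ids[j], alignment_score = score)
  })
  edges <- dplyr::filter(edges, .data$alignment_score >= alignment_score_threshold)
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  if (nrow(edges) > 0) igraph::E(g)$alignment_score <- edges$alignment_score
  structure(
    list(graph = g, edges = edges, threshold = alignment_score_threshold,
         proteins = proteins[, c("id", "sequence")], repnode_map = NULL,
         repnode_identity = NA_real_),
    class = "rre_ssn"
  )
}

#' @export
print.rre_ssn <- function(x, ...) {
  cat("<rre_ssn> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (threshold ", x$threshold, ")\n",
      sep = "")
  if (!is.null(x$repnode_map)) {
    cat("  RepNode", round(100 * x$repnode_identity), " conflation applied\n",
        sep = "")
  }
  invisible(x)
}

#' Conflate an SSN into representative nodes
#'
#' Sequences sharing at least the stated identity (via
#' [greedy_cluster()]) collapse onto one representative node (RepNode60 /
#' RepNode80 in the published networks); edges are re-attached between
#' representatives and de-duplicated, keeping the best alignment score.
#'
#' @param ssn An [build_ssn()] result.
#' @param identity Conflation identity (0.60 or 0.80 in the published
#'   networks).
#' @return A new `rre_ssn` over the representatives, with `repnode_map`
#'   giving id -> representative.
#' @export
conflate_repnodes <- function(ssn, identity = 0.80) {
  stopifnot(inherits(ssn, "rre_ssn"))
  cl <- greedy_cluster(ssn$proteins, identity_threshold = identity)
  map <- stats::setNames(cl$representative, cl$id)
  edges <- ssn$edges
  if (nrow(edges) > 0) {
    edges$id_a <- unname(map[edges$id_a])
    edges$id_b <- unname(map[edges$id_b])
    swap <- edges$id_a > edges$id_b
    tmp <- edges$id_a[swap]; edges$id_a[swap] <- edges$id_b[swap]
    edges$id_b[swap] <- tmp
    edges <- dplyr::filter(edges, .data$id_a != .data$id_b)
    if (nrow(edges) > 0) {
      edges <- edges |>
        dplyr::group_by(.data$id_a, .data$id_b) |>
        dplyr::summarise(alignment_score = max(.data$alignment_score),
                         .groups = "drop")
    }
  }
  reps <- unique(unname(map))
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = reps)
  )
  if (nrow(edges) > 0) igraph::E(g)$alignment_score <- edges$alignment_score
  structure(
    list(graph = g, edges = edges, threshold = ssn$threshold,
         proteins = ssn$proteins[ssn$proteins$id %in% reps, , drop = FALSE],
         repnode_map = tibble::tibble(id = names(map), repnode = unname(map)),
         repnode_identity = identity),
    class = "rre_ssn"
  )
}

#' Select diverse seed sequences from an SSN
#'
#' One member per connected component, components visited in
#' size-descending order, until `min(k_max, n_components)` seeds are
#' collected; when there are fewer components than `k_min`, the largest
#' components contribute additional members round-robin.  Within a
#' component the member is drawn at random, so the selection is
#' deterministic given `seed`.  This mirrors picking 5-20 representative
#' sequences from divergent SSN clusters for a seed alignment.
#'
#' @param ssn An `rre_ssn`.
#' @param k_range Length-2 integer vector `(k_min, k_max)`.
#' @param seed RNG seed.
#' @return Character vector of selected sequence ids.
#' @export
select_diverse_seeds <- function(ssn, k_range = c(5L, 20L), seed = 1) {
  stopifnot(inherits(ssn, "rre_ssn"))
  if (igraph::vcount(ssn$graph) == 0) stop("empty SSN graph")
  comp <- igraph::components(ssn$graph)
  members <- split(names(comp$membership), comp$membership)
  members <- members[order(-lengths(members),
                           vapply(members, min, character(1)))]
  with_seed(seed, {
    shuffled <- lapply(members, function(m) sample(m, length(m)))
    k_min <- k_range[1]; k_max <- k_range[2]
    n_comp <- length(shuffled)
    target <- max(min(k_max, n_comp), min(k_min, sum(lengths(shuffled))))
    picks <- character(0)
    round <- 1
    while (length(picks) < target) {
      added <- FALSE
      for (m in shuffled) {
        if (length(picks) >= target) break
        if (length(m) >= round) {
          picks <- c(picks, m[round])
          added <- TRUE
        }
      }
      if (!added) break
      round <- round + 1
    }
    picks
  })
}

#' Export an SSN as edge-list and node-attribute tables
#'
#' Writes `"<prefix>_edges.tsv"` (`id_a`, `id_b`, `alignment_score`) and
#' `"<prefix>_nodes.tsv"` (`id`, `repnode`, `component`), loadable by
#' standard graph viewers.
#'
#' @param ssn An `rre_ssn`.
#' @param prefix Output path prefix.
#' @param node_attrs Optional tibble keyed by `id` with extra node
#'   columns (e.g. `best_model`, `class_tag`) merged into the node table.
#' @return The two paths, invisibly.
#' @export
export_ssn <- function(ssn, prefix, node_attrs = NULL) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  utils::write.table(ssn$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  comp <- igraph::components(ssn$graph)
  nodes <- tibble::tibble(
    id = names(comp$membership),
    component = unname(comp$membership)
  )
  if (!is.null(ssn$repnode_map)) {
    nodes <- dplyr::left_join(nodes, ssn$repnode_map, by = "id")
  } else {
    nodes$repnode <- nodes$id
  }
  if (!is.null(node_attrs)) nodes <- dplyr::left_join(nodes, node_attrs, by = "id")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges = edge_path, nodes = node_path))
}
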