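#' Greedy identity clustering
#'
#' Longest-first greedy clustering: sequences are sorted by length
#' descending (ties by id); each sequence joins the first existing
#' cluster whose representative it matches at or above the identity
#' threshold (identity from [global_align()]), otherwise it founds a new
#' cluster.  Cluster representatives are therefore the longest members.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param identity_threshold Minimum pairwise identity (default 0.80, the
#'   de-duplication level used when building the exploratory database).
#' @return Tibble with columns `id`, `sequence`, `cluster`,
#'   `representative`, of class `rre_clusters`; clusters partition the
#'   input.
#' @export
greedy_cluster <- function(proteins, identity_threshold = 0.80) {
  stopifnot(nrow(proteins) >= 1)
  ord <- order(-nchar(proteins$sequence), proteins$id)
  p <- proteins[ord, , drop = FALSE]
  reps <- character(0)      # representative ids
  rep_seq <- character(0)
  assignment <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      ga <- global_align(p$sequence[[i]], rep_seq[[k]])
      if (ga$identity >= identity_threshold) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, p$id[[i]])
      rep_seq <- c(rep_seq, p$sequence[[i]])
      assignment[i] <- length(reps)
    }
  }
  out <- tibble::tibble(
    id = p$id, sequence = p$sequence,
    cluster = assignment,
    representative = reps[assignment]
  )
  class(out) <- c("rre_clusters", class(out))
  out
}

cluster_representatives <- function(clusters) {
  dplyr::distinct(tibble::as_tibble(clusters)[clusters$id == clusters$representative,
                                              c("id", "sequence")])
}
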