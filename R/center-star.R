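#' Center-star multiple sequence alignment
#'
#' Minimal progressive aligner for seed sets: the center is the sequence
#' maximising the summed pairwise global alignment score against all
#' others (ties by id); every other sequence is merged onto the center's
#' coordinate frame with the usual "once a gap, always a gap" rule.
#'
#' @param proteins Protein tibble (`id`, `sequence`), >= 2 rows.
#' @return An [rre_alignment] with rows in input order.
#' @export
msa_center_star <- function(proteins) {
  n <- nrow(proteins)
  if (n < 2) stop("center-star alignment needs at least 2 sequences")
  score_sum <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s <- global_align(proteins$sequence[[i]], proteins$sequence[[j]])$score
      score_sum[i] <- score_sum[i] + s
      score_sum[j] <- score_sum[j] + s
    }
  }
  center <- order(-score_sum, proteins$id)[1]

  master <- proteins$sequence[[center]]   # gapped center
  rows <- list()                          # gapped others, in master frame
  other_idx <- setdiff(seq_len(n), center)
  for (i in other_idx) {
    ga <- global_align(gsub("-", "", master), proteins$sequence[[i]])
    new_center <- ga$alignment[1]
    new_row <- ga$alignment[2]
    # merge the new pairwise center coordinates with the existing master:
    # walk both center strings, inserting gaps where they disagree
    merged <- merge_center_frames(master, new_center)
    master_new <- merged$merged
    # re-express existing rows and the new row in the merged frame
    rows <- lapply(rows, expand_row, positions = merged$old_map,
                   width = nchar(master_new))
    rows[[length(rows) + 1]] <- expand_row(new_row, merged$new_map,
                                           nchar(master_new))
    master <- master_new
  }
  ids <- c(proteins$id[center], proteins$id[other_idx])
  aligned <- c(master, unlist(rows))
  ord <- match(proteins$id, ids)
  rre_alignment(proteins$id, aligned[ord])
}

# Merge two gapped versions of the same ungapped center sequence into one
# frame containing the union of gaps.  Returns the merged center string and,
# for each input frame, the mapping old column -> merged column.
merge_center_frames <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  ia <- 1; ib <- 1
  merged <- character(0)
  old_map <- integer(length(ca))
  new_map <- integer(length(cb))
  while (ia <= length(ca) || ib <= length(cb)) {
    cha <- if (ia <= length(ca)) ca[ia] else NULL
    chb <- if (ib <= length(cb)) cb[ib] else NULL
    if (!is.null(cha) && cha == "-" && (is.null(chb) || chb != "-")) {
      merged <- c(merged, "-")
      old_map[ia] <- length(merged); ia <- ia + 1
    } else if (!is.null(chb) && chb == "-" && (is.null(cha) || cha != "-")) {
      merged <- c(merged, "-")
      new_map[ib] <- length(merged); ib <- ib + 1
    } else {
      # both gap, or both the same residue
      merged <- c(merged, cha)
      old_map[ia] <- length(merged)
      new_map[ib] <- length(merged)
      ia <- ia + 1; ib <- ib + 1
    }
  }
  list(merged = paste(merged, collapse = ""), old_map = old_map,
       new_map = new_map)
}

# Re-express a gapped row (aligned to an old frame) in the merged frame.
expand_row <- function(row, positions, width) {
  chars <- rep("-", width)
  rc <- seq_chars(row)
  chars[positions] <- rc
  paste(chars, collapse = "")
}
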