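#' Sample sequences from a profile HMM
#'
#' Stochastic traversal of the model from the first to the last position:
#' begin enters match state 1; match and insert states emit from their
#' emission distributions; `M->I`/`I->I`/`I->M` runs produce insertions
#' and `M->D`/`D->D` runs produce deletions.  Deterministic given `seed`.
#'
#' @param hmm A [profile_hmm].
#' @param n Number of sequences (>= 1).
#' @param seed RNG seed.
#' @param prefix Id prefix for the sampled records.
#' @return Protein tibble with an extra `aligned` column: the sampled
#'   residues laid out over the model's match positions (deletions as
#'   `-`, insertions dropped), directly usable as generator-coordinate
#'   alignment rows.
#' @export
sample_from_phmm <- function(hmm, n, seed = 1, prefix = "s") {
  stopifnot(n >= 1)
  tr <- hmm$transitions
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      seq_parts <- character(0)
      aligned <- character(hmm$M)
      state <- "M"
      j <- 1
      while (j <= hmm$M) {
        if (state == "M") {
          a <- sample(AA20, 1, prob = hmm$match_emissions[j, ])
          seq_parts <- c(seq_parts, a)
          aligned[j] <- a
          if (j == hmm$M) break
          mv <- sample(c("MM", "MI", "MD"), 1, prob = tr[j, 1:3])
          if (mv == "MI") {
            repeat {
              seq_parts <- c(seq_parts,
                             sample(AA20, 1, prob = hmm$insert_emissions[j + 1, ]))
              if (sample(c("IM", "II"), 1, prob = tr[j, 4:5]) == "IM") break
            }
            state <- "M"
          } else if (mv == "MD") {
            state <- "D"
          }
          j <- j + 1
        } else {
          aligned[j] <- "-"
          if (j == hmm$M) break
          state <- if (sample(c("DM", "DD"), 1, prob = tr[j, 6:7]) == "DM") "M" else "D"
          j <- j + 1
        }
      }
      list(sequence = paste(seq_parts, collapse = ""),
           aligned = paste(aligned, collapse = ""))
    })
    tibble::tibble(
      id = sprintf("%s%03d", prefix, seq_len(n)),
      description = paste0("sampled from ", hmm$name),
      sequence = vapply(rows, `[[`, character(1), "sequence"),
      aligned = vapply(rows, `[[`, character(1), "aligned")
    )
  })
}

#' Expected emitted length of a sampled sequence
#'
#' Closed-form expectation under the traversal used by
#' [sample_from_phmm()]: state-occupancy probabilities are propagated
#' through the transition matrix and insert runs contribute geometric
#' expected counts `1 / (1 - t_II)`.
#'
#' @param hmm A [profile_hmm].
#' @return Expected number of emitted residues.
#' @export
phmm_expected_length <- function(hmm) {
  tr <- hmm$transitions
  M <- hmm$M
  pM <- numeric(M); pD <- numeric(M)
  pM[1] <- 1
  if (M > 1) {
    for (j in seq_len(M - 1)) {
      pM[j + 1] <- pM[j] * (tr[j, "MM"] + tr[j, "MI"]) + pD[j] * tr[j, "DM"]
      pD[j + 1] <- pM[j] * tr[j, "MD"] + pD[j] * tr[j, "DD"]
    }
  }
  exp_match <- sum(pM)
  exp_ins <- if (M > 1) {
    sum(vapply(seq_len(M - 1), function(j) {
      pM[j] * tr[j, "MI"] * (1 / (1 - tr[j, "II"]))
    }, numeric(1)))
  } else 0
  exp_match + exp_ins
}
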