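# Emission log-odds (bits) for one sequence against a model: L x M matrix.
# X residues (NA index) emit the background and contribute 0 bits.
match_lodds_matrix <- function(hmm, sequence) {
  idx <- seq_to_idx(sequence)
  lod <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))  # M x 20
  out <- matrix(0, nrow = length(idx), ncol = hmm$M)
  ok <- !is.na(idx)
  if (any(ok)) out[ok, ] <- t(lod[, idx[ok], drop = FALSE])
  out
}

log2_transitions <- function(hmm) {
  suppressWarnings(log2(hmm$transitions))
}

# Raw local Viterbi: returns score/envelope/path even when the score is
# non-positive (callers decide whether that constitutes a hit).
viterbi_raw <- function(hmm, sequence) {
  if (nchar(sequence) < 1) stop("protein sequence must have length >= 1")
  res <- viterbi_local_cpp(match_lodds_matrix(hmm, sequence),
                           log2_transitions(hmm), log2(1 / hmm$M))
  res
}

#' Score a protein with a profile HMM (local Viterbi)
#'
#' Dynamic programming over match/insert/delete states with uniform local
#' entry (probability 1/M into any match state), free exit after any match
#' state, and flanking residues scored only under the null.  The bit score
#' is the maximal path log2-odds (emissions relative to background plus
#' transition probabilities).  Returns the best hit with its envelope
#' (first/last match-emitted residue, 1-based inclusive), or a zero-row
#' hit table when the maximal score is not positive.
#'
#' @param hmm A [profile_hmm].
#' @param protein A single-row protein tibble, or a list/row with `id` and
#'   `sequence`, or a plain sequence string.
#' @param config An [rre_config] used for tier labels.
#' @return A hit tibble with columns `protein_id`, `model_name`,
#'   `bit_score`, `evalue`, `env_from`, `env_to`, `ali_len`, `tiers`
#'   (list column), `best_fit`, `regulator_flag`; zero rows if no positive
#'   score.
#' @export
score_viterbi <- function(hmm, protein, config = rre_config()) {
  p <- as_protein_row(protein)
  res <- viterbi_raw(hmm, p$sequence)
  if (!is.finite(res$score) || res$score <= 0) return(empty_hits())
  ev <- if (!is.na(hmm$gumbel_mu)) evalue_from_bits(hmm, res$score) else NA_real_
  tibble::tibble(
    protein_id = p$id,
    model_name = hmm$name,
    bit_score = res$score,
    evalue = ev,
    env_from = res$env_from,
    env_to = res$env_to,
    ali_len = res$env_to - res$env_from + 1L,
    tiers = list(assign_tiers(res$score, config)),
    best_fit = FALSE,
    regulator_flag = FALSE
  )
}

#' Forward (summed) bit score of a protein under a model
#'
#' Log-sum-exp over the same local path space as [score_viterbi()]; always
#' at least the Viterbi bit score.
#'
#' @inheritParams score_viterbi
#' @return Forward score in bits.
#' @export
score_forward <- function(hmm, protein) {
  p <- as_protein_row(protein)
  if (nchar(p$sequence) < 1) stop("protein sequence must have length >= 1")
  forward_local_cpp(match_lodds_matrix(hmm, p$sequence),
                    log2_transitions(hmm), log2(1 / hmm$M))
}

#' Scan a protein table with a set of models
#'
#' Every model against every protein; one best envelope per
#' (protein, model) pair; hits kept at `bit_cutoff` and tier-labelled.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param models A list of [profile_hmm] objects.
#' @param bit_cutoff Minimum bit score to report.
#' @param config An [rre_config].
#' @return Hit tibble sorted by `protein_id`, then descending `bit_score`.
#' @export
scan_proteins <- function(proteins, models, bit_cutoff = 25,
                          config = rre_config()) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  stopifnot(length(models) >= 1)
  hits <- purrr::map_dfr(models, function(hmm) {
    purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
      score_viterbi(hmm, proteins[i, ], config = config)
    })
  })
  if (nrow(hits) == 0) return(empty_hits())
  hits |>
    dplyr::filter(.data$bit_score >= bit_cutoff) |>
    dplyr::arrange(.data$protein_id, dplyr::desc(.data$bit_score))
}

empty_hits <- function() {
  tibble::tibble(
    protein_id = character(0), model_name = character(0),
    bit_score = numeric(0), evalue = numeric(0),
    env_from = integer(0), env_to = integer(0), ali_len = integer(0),
    tiers = list(), best_fit = logical(0), regulator_flag = logical(0)
  )
}

as_protein_row <- function(protein) {
  if (is.character(protein) && length(protein) == 1 && is.null(names(protein))) {
    return(list(id = "query", sequence = protein))
  }
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1)
    return(list(id = protein$id[[1]], sequence = protein$sequence[[1]]))
  }
  list(id = protein$id, sequence = protein$sequence)
}
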