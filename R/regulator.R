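#' Bundle regulator / helix-turn-helix filter models
#'
#' DNA-binding regulators and other helix-turn-helix (HTH) domains are
#' structurally homologous to RREs and are the dominant false-positive
#' class; this set of profile HMMs, each with a trusted bit-score cutoff,
#' drives [regulator_filter()].
#'
#' @param models List of [profile_hmm] objects, each with a finite
#'   `trusted_cutoff`.
#' @param notes Free-text provenance notes.
#' @return Object of class `regulator_model_set`.
#' @export
regulator_model_set <- function(models, notes = "") {
  if (inherits(models, "profile_hmm")) models <- list(models)
  ok <- vapply(models, function(m) is.finite(m$trusted_cutoff), logical(1))
  if (!all(ok)) {
    stop("regulator model(s) without trusted_cutoff: ",
         paste(vapply(models[!ok], `[[`, character(1), "name"), collapse = ", "),
         call. = FALSE)
  }
  structure(list(models = models, notes = notes),
            class = "regulator_model_set")
}

#' @export
print.regulator_model_set <- function(x, ...) {
  cat("<regulator_model_set> ", length(x$models), " models\n", sep = "")
  invisible(x)
}

#' Flag hits overlapping regulator domains
#'
#' Each hit's parent protein is scanned against every regulator model at
#' that model's trusted cutoff; the hit is flagged when a regulator match
#' at or above its trusted cutoff overlaps the RRE envelope by at least
#' one residue.  Flagged hits are retained with `regulator_flag = TRUE`
#' (removal is left to the caller), mirroring an output file that marks
#' regulator overlap rather than silently dropping hits.
#'
#' @param hits Hit tibble.
#' @param proteins Protein tibble containing all hit parents.
#' @param regulator_models A [regulator_model_set].
#' @return The hit tibble with `regulator_flag` set.
#' @export
regulator_filter <- function(hits, proteins, regulator_models) {
  if (!inherits(regulator_models, "regulator_model_set")) {
    regulator_models <- regulator_model_set(regulator_models)
  }
  if (nrow(hits) == 0) return(hits)
  parents <- unique(hits$protein_id)
  reg_hits <- lapply(stats::setNames(parents, parents), function(pid) {
    p <- proteins[proteins$id == pid, , drop = FALSE]
    stopifnot(nrow(p) == 1)
    purrr::map_dfr(regulator_models$models, function(m) {
      r <- viterbi_raw(m, p$sequence[[1]])
      if (is.finite(r$score) && r$score >= m$trusted_cutoff) {
        tibble::tibble(from = r$env_from, to = r$env_to)
      } else {
        tibble::tibble(from = integer(0), to = integer(0))
      }
    })
  })
  hits$regulator_flag <- vapply(seq_len(nrow(hits)), function(i) {
    rh <- reg_hits[[hits$protein_id[[i]]]]
    if (nrow(rh) == 0) return(FALSE)
    any(pmin(rh$to, hits$env_to[[i]]) - pmax(rh$from, hits$env_from[[i]]) >= 0)
  }, logical(1))
  hits
}
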