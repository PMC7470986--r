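#' Write a hit table to TSV
#'
#' One row per hit: `protein_id`, `model`, `bit_score` (2 decimals),
#' `evalue` (scientific, 2 significant figures, `NA` when uncalibrated),
#' `env_from`, `env_to` (1-based inclusive), `tiers` (comma-joined),
#' `best_fit`, `regulator_flag`; sorted by `protein_id` then descending
#' bit score.  An empty hit table yields a header-only file.
#'
#' @param hits Hit tibble as produced by [precision_scan()] and friends.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- tibble::tibble(
    protein_id = hits$protein_id,
    model = hits$model_name,
    bit_score = sprintf("%.2f", hits$bit_score),
    evalue = ifelse(is.na(hits$evalue), "NA",
                    sprintf("%.1e", hits$evalue)),
    env_from = hits$env_from,
    env_to = hits$env_to,
    tiers = vapply(hits$tiers, paste, character(1), collapse = ","),
    best_fit = hits$best_fit,
    regulator_flag = hits$regulator_flag
  )
  out <- out[order(out$protein_id, -hits$bit_score), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hit table written by [write_hits_tsv()]
#'
#' @param path TSV path.
#' @return Hit tibble (with `tiers` re-split into a list column).
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty_hits())
  tibble::tibble(
    protein_id = as.character(df$protein_id),
    model_name = as.character(df$model),
    bit_score = as.numeric(df$bit_score),
    evalue = suppressWarnings(as.numeric(df$evalue)),
    env_from = as.integer(df$env_from),
    env_to = as.integer(df$env_to),
    ali_len = as.integer(df$env_to) - as.integer(df$env_from) + 1L,
    tiers = lapply(strsplit(as.character(df$tiers), ","), function(x) x[nzchar(x)]),
    best_fit = as.logical(df$best_fit),
    regulator_flag = as.logical(df$regulator_flag)
  )
}
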