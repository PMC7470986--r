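#' Read a protein FASTA file into a protein table
#'
#' Parses a (possibly multi-record) FASTA file via [Biostrings::readBStringSet()]
#' and normalises it into the package's tabular protein representation:
#' sequences are upper-cased, `*` stop characters are stripped, and the
#' non-canonical residues B/Z/U/O are mapped to `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, one row
#'   per record, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  seqs <- vapply(seq_along(seqs), function(i) {
    s <- normalize_residues(seqs[[i]], ids[[i]])
    if (!nzchar(s)) stop("empty sequence for record '", ids[[i]], "'", call. = FALSE)
    s
  }, character(1))
  tibble::tibble(id = ids, description = desc, sequence = unname(seqs))
}

#' Write a protein table to FASTA
#'
#' @param proteins Tibble with `id`, `sequence` and optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  headers <- proteins$id
  if ("description" %in% names(proteins)) {
    has_desc <- !is.na(proteins$description) & nzchar(proteins$description)
    headers[has_desc] <- paste(proteins$id[has_desc], proteins$description[has_desc])
  }
  set <- Biostrings::BStringSet(stats::setNames(proteins$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

new_protein_tbl <- function(id, sequence, description = "") {
  tibble::tibble(id = id, description = description, sequence = sequence)
}
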