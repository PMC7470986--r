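#' Construct an alignment object from gapped rows
#'
#' The package's multiple-sequence-alignment container: equal-length gapped
#' rows over the amino-acid alphabet, with `.` and `-` both accepted as gap
#' characters on input and normalised to `-`.
#'
#' @param ids Character vector of row ids.
#' @param rows Character vector of gapped sequences (same length as `ids`).
#' @return An object of class `rre_alignment` with elements `rows`
#'   (a tibble of `id`, `aligned`) and `n_columns`.
#' @export
rre_alignment <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), length(ids) >= 1)
  rows <- toupper(chartr(".", "-", rows))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    ragged <- ids[widths != widths[1]]
    stop("ragged alignment rows: ", paste(ragged, collapse = ", "), call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) stop("duplicate row ids: ", paste(dup, collapse = ", "))
  for (i in seq_along(rows)) {
    degapped <- gsub("-", "", rows[[i]], fixed = TRUE)
    rows[[i]] <- gsub("-", "-", rows[[i]])  # keep gaps
    # validate the de-gapped residues (also normalises nothing in place:
    # alignment rows must already be canonical)
    normalize_residues(degapped, ids[[i]])
  }
  structure(
    list(rows = tibble::tibble(id = ids, aligned = rows),
         n_columns = widths[1]),
    class = "rre_alignment"
  )
}

#' @export
print.rre_alignment <- function(x, ...) {
  cat("<rre_alignment> ", nrow(x$rows), " rows x ", x$n_columns, " columns\n",
      sep = "")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm.  Stockholm markup lines (`#=GF`,
#' `#=GC`, `#=GS`, `#=GR`) and the trailing `//` are ignored; sequence
#' lines for the same id across blocks are concatenated.  `.` and `-` are
#' both accepted as gaps.
#'
#' @param path File path.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @return An [rre_alignment] object.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "stockholm")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                     nzchar(trimws(lines))]
    lines <- lines[!grepl("^# STOCKHOLM", lines)]
    parts <- strsplit(trimws(lines), "\\s+")
    ok <- lengths(parts) == 2
    parts <- parts[ok]
    if (length(parts) == 0) stop("no sequence rows found in ", path)
    ids_all <- vapply(parts, `[[`, character(1), 1)
    seq_all <- vapply(parts, `[[`, character(1), 2)
    ids <- unique(ids_all)
    rows <- vapply(ids, function(id) {
      paste(seq_all[ids_all == id], collapse = "")
    }, character(1))
  }
  if (length(ids) < 2) {
    stop("alignment must contain at least 2 rows, found ", length(ids),
         call. = FALSE)
  }
  rre_alignment(unname(ids), unname(rows))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An [rre_alignment].
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "rre_alignment"))
  set <- Biostrings::BStringSet(stats::setNames(aln$rows$aligned, aln$rows$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Matrix of residue characters (rows x columns) for an alignment.
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows$aligned, "", fixed = TRUE))
}
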