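# The 20 canonical amino acids, in the fixed column order used by every
# emission matrix in the package; 'X' is the only other residue allowed.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Uniform amino-acid background distribution
#'
#' The default null model: every canonical residue at probability 1/20.
#' A named probability vector over the 20 canonical amino acids can be
#' supplied anywhere a `background` argument is accepted.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

# Split a sequence string into residue characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Map a protein string to integer indices into AA20; X (and the ambiguity
# codes B/Z/U/O, already normalised to X on input) come back as NA and are
# scored with the background (0 bits log-odds).
seq_to_idx <- function(x) {
  match(seq_chars(x), AA20)
}

# Normalise a raw sequence: upper-case, strip '*' stops, map the
# non-canonical codes B/Z/U/O (and J) to X.  Errors on anything else.
normalize_residues <- function(x, id = "<sequence>") {
  x <- toupper(gsub("*", "", x, fixed = TRUE))
  has_odd <- grepl("[BZUOJ]", x)
  x <- chartr("BZUOJ", "XXXXX", x)
  bad <- regmatches(x, regexpr(sprintf("[^%sX]", paste(AA20, collapse = "")), x))
  if (length(bad) > 0 && nzchar(bad[[1]])) {
    stop("illegal residue character '", bad[[1]], "' in record '", id, "'",
         call. = FALSE)
  }
  if (has_odd) {
    warning("non-standard residues (B/Z/U/O) in '", id, "' mapped to X",
            call. = FALSE)
  }
  x
}

validate_background <- function(background) {
  if (is.null(background)) return(uniform_background())
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-6)
  if (is.null(names(background))) names(background) <- AA20
  background[AA20]
}
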