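#' Construct a biosynthetic gene cluster locus
#'
#' An ordered list of genes along one locus.  Gene order follows genomic
#' start coordinate regardless of strand; `gene_index` numbers the genes
#' 1..n in that order and differences of `gene_index` are the ORF
#' distances used by the co-occurrence rules.
#'
#' @param locus_id Locus identifier.
#' @param genes Tibble with columns `id`, `strand` (`"+"`/`"-"`),
#'   `translation`, and optionally `start`, `end`, `annotations`
#'   (a list column of character vectors of domain-model names).
#' @return Object of class `bgc_locus`.
#' @export
bgc_locus <- function(locus_id, genes) {
  stopifnot(is.character(locus_id), nrow(genes) >= 1)
  if (!"annotations" %in% names(genes)) {
    genes$annotations <- replicate(nrow(genes), character(0), simplify = FALSE)
  }
  if (!"start" %in% names(genes)) genes$start <- seq_len(nrow(genes))
  if (any(!nzchar(genes$translation))) stop("empty translation in locus ", locus_id)
  genes <- genes[order(genes$start), , drop = FALSE]
  genes$gene_index <- seq_len(nrow(genes))
  genes$translation <- vapply(seq_len(nrow(genes)), function(i) {
    normalize_residues(genes$translation[[i]], genes$id[[i]])
  }, character(1))
  structure(list(locus_id = locus_id,
                 genes = tibble::as_tibble(genes)),
            class = "bgc_locus")
}

#' @export
print.bgc_locus <- function(x, ...) {
  cat("<bgc_locus> ", x$locus_id, ": ", nrow(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Proteins of a locus as a protein table
#'
#' Gene translations with ids of the form `"<locus_id>|<gene_id>"`, the
#' join key used by the validation functions.
#'
#' @param locus A [bgc_locus].
#' @return Protein tibble (`id`, `description`, `sequence`) plus `source`
#'   columns `locus_id` and `gene_index`.
#' @export
locus_proteins <- function(locus) {
  g <- locus$genes
  tibble::tibble(
    id = paste(locus$locus_id, g$id, sep = "|"),
    description = "",
    sequence = g$translation,
    locus_id = locus$locus_id,
    gene_index = g$gene_index
  )
}

# ---- GenBank flat-file reading -------------------------------------------

#' Read GenBank CDS features into loci
#'
#' Minimal GenBank flat-file reader covering what gene-neighborhood
#' analysis needs: CDS features with `/translation` qualifiers (or, when
#' absent, coordinates translatable from the ORIGIN nucleotide record).
#' Genes are ordered by start coordinate irrespective of strand.  A CDS
#' with no `/translation` whose nucleotide span contains ambiguous bases
#' is skipped with a warning.  Multi-record files yield one locus per
#' record.
#'
#' @param path Path to a GenBank flat file.
#' @return A [bgc_locus], or a list of them for multi-record files.
#' @export
read_genbank_locus <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  rec_breaks <- grep("^//", lines)
  if (length(rec_breaks) == 0) rec_breaks <- length(lines)
  starts <- c(1, utils::head(rec_breaks, -1) + 1)
  loci <- list()
  for (r in seq_along(rec_breaks)) {
    rec <- lines[starts[r]:rec_breaks[r]]
    if (!any(grepl("^LOCUS", rec))) next
    loci[[length(loci) + 1]] <- parse_genbank_record(rec, path)
  }
  if (length(loci) == 0) stop("no GenBank records found in ", path)
  if (length(loci) == 1) loci[[1]] else loci
}

parse_genbank_record <- function(rec, path) {
  locus_line <- rec[grepl("^LOCUS", rec)][1]
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus_line)), "\\s+")[[1]][1]

  feat_from <- grep("^FEATURES", rec)
  origin_at <- grep("^ORIGIN", rec)
  feat_to <- if (length(origin_at)) origin_at[1] - 1 else length(rec)
  nt <- ""
  if (length(origin_at)) {
    seq_lines <- rec[(origin_at[1] + 1):length(rec)]
    nt <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }
  if (length(feat_from) == 0) stop("no FEATURES section in record ", locus_id)
  flines <- rec[(feat_from[1] + 1):feat_to]

  # feature key lines have the key in columns 6-20
  is_key <- grepl("^ {5}\\S", flines)
  key_idx <- which(is_key)
  keys <- trimws(substr(flines[key_idx], 6, 20))
  cds_idx <- key_idx[keys == "CDS"]
  if (length(cds_idx) == 0) {
    stop("record ", locus_id, " contains no CDS features", call. = FALSE)
  }

  genes <- list()
  for (k in seq_along(cds_idx)) {
    i0 <- cds_idx[k]
    i1 <- if (any(key_idx > i0)) min(key_idx[key_idx > i0]) - 1 else length(flines)
    block <- flines[i0:i1]
    body <- trimws(substr(block, 22, nchar(block)))
    # location spans lines up to the first qualifier
    qual_at <- grep("^/", body)
    loc_to <- if (length(qual_at)) qual_at[1] - 1 else length(body)
    loc <- paste(body[1:loc_to], collapse = "")
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    gstart <- min(nums); gend <- max(nums)

    quals <- paste(body[seq_along(body) > loc_to], collapse = "\n")
    translation <- extract_qualifier(quals, "translation")
    gid <- extract_qualifier(quals, "locus_tag")
    if (is.na(gid)) gid <- extract_qualifier(quals, "gene")
    if (is.na(gid)) gid <- sprintf("cds_%d", k)

    if (is.na(translation)) {
      if (!nzchar(nt)) {
        warning("CDS ", gid, " in ", locus_id,
                " has no /translation and no ORIGIN sequence; skipped")
        next
      }
      cds_nt <- substr(nt, gstart, gend)
      if (grepl("[^ACGT]", cds_nt)) {
        warning("CDS ", gid, " in ", locus_id,
                " has ambiguous codons and no /translation; skipped")
        next
      }
      dna <- Biostrings::DNAString(cds_nt)
      if (strand == "-") dna <- Biostrings::reverseComplement(dna)
      aa <- as.character(Biostrings::translate(dna, no.init.codon = TRUE))
      translation <- sub("\\*$", "", aa)
    } else {
      translation <- gsub("[\\s\n]", "", translation, perl = TRUE)
    }
    genes[[length(genes) + 1]] <- tibble::tibble(
      id = gid, strand = strand, start = gstart, end = gend,
      translation = translation
    )
  }
  if (length(genes) == 0) {
    stop("record ", locus_id, " contains no usable CDS features", call. = FALSE)
  }
  bgc_locus(locus_id, dplyr::bind_rows(genes))
}

extract_qualifier <- function(quals, name) {
  pat <- sprintf("/%s=\"([^\"]*)\"", name)
  m <- regmatches(quals, regexec(pat, quals))[[1]]
  if (length(m) < 2) {
    pat2 <- sprintf("/%s=([^\n/]+)", name)
    m <- regmatches(quals, regexec(pat2, quals))[[1]]
    if (length(m) < 2) return(NA_character_)
  }
  trimws(m[2])
}

# ---- GenBank writing (fixture support) -----------------------------------

# one fixed codon per amino acid keeps fixture nucleotide records exact
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              X = "GCT")

reverse_translate <- function(aa) {
  paste(CODON_OF[seq_chars(aa)], collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Write a locus as a GenBank flat file
#'
#' Emits a self-consistent record: each gene's translation is
#' reverse-translated with a fixed codon table, laid out along the locus
#' with short intergenic spacers, and written with CDS features carrying
#' `/locus_tag` and `/translation` qualifiers plus the full ORIGIN
#' nucleotide sequence.  Round-trips through [read_genbank_locus()].
#'
#' @param locus A [bgc_locus].
#' @param path Output path.
#' @param spacer Intergenic spacer length in nucleotides.
#' @param include_translation Emit `/translation` qualifiers (disable to
#'   exercise the translate-from-ORIGIN path of the reader).
#' @export
write_genbank_locus <- function(locus, path, spacer = 20L,
                                include_translation = TRUE) {
  g <- locus$genes
  nt_parts <- character(0)
  pos <- 1L
  feats <- character(0)
  spacer_nt <- paste(rep("ACGT", ceiling(spacer / 4)), collapse = "")
  spacer_nt <- substr(spacer_nt, 1, spacer)
  for (i in seq_len(nrow(g))) {
    cds <- paste0(reverse_translate(g$translation[[i]]), "TAA")
    span <- nchar(cds)
    placed <- if (g$strand[[i]] == "-") revcomp_chr(cds) else cds
    nt_parts <- c(nt_parts, placed, spacer_nt)
    loc <- sprintf("%d..%d", pos, pos + span - 1L)
    if (g$strand[[i]] == "-") loc <- sprintf("complement(%s)", loc)
    feats <- c(feats,
               sprintf("     CDS             %s", loc),
               sprintf("                     /locus_tag=\"%s\"", g$id[[i]]))
    if (include_translation) {
      feats <- c(feats, wrap_qualifier("translation", g$translation[[i]]))
    }
    pos <- pos + span + nchar(spacer_nt)
  }
  nt <- paste(nt_parts, collapse = "")
  out <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   SYN", locus$locus_id, nchar(nt)),
    sprintf("DEFINITION  synthetic fixture locus %s.", locus$locus_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(nt)),
    feats,
    "ORIGIN",
    format_origin(nt),
    "//"
  )
  writeLines(out, path)
  invisible(path)
}

wrap_qualifier <- function(name, value, width = 58L) {
  txt <- sprintf("/%s=\"%s\"", name, value)
  pieces <- substring(txt, seq(1, nchar(txt), by = width),
                      pmin(seq(1, nchar(txt), by = width) + width - 1, nchar(txt)))
  paste0(strrep(" ", 21), pieces)
}

format_origin <- function(nt) {
  n <- nchar(nt)
  starts <- seq(1, n, by = 60)
  vapply(starts, function(s) {
    chunk <- substr(nt, s, min(s + 59, n))
    groups <- substring(chunk, seq(1, nchar(chunk), by = 10),
                        pmin(seq(1, nchar(chunk), by = 10) + 9, nchar(chunk)))
    sprintf("%9d %s", s, paste(tolower(groups), collapse = " "))
  }, character(1))
}
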