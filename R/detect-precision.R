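#' Assign bit-score tiers
#'
#' The tolerant/moderate/stringent tiers are nested: a score qualifies
#' for every tier whose cutoff it reaches (defaults 15/25/35 bits).
#'
#' @param bit_score Bit score.
#' @param config An [rre_config].
#' @return Character vector, a subset of
#'   `c("tolerant", "moderate", "stringent")`.
#' @export
assign_tiers <- function(bit_score, config = rre_config()) {
  names(config$tier_bits)[bit_score >= config$tier_bits]
}

#' Precision-mode scan
#'
#' Scores every model of a class-specific library against every protein,
#' keeps hits at `bit_cutoff`, labels tiers, and marks `best_fit = TRUE`
#' on each protein's maximal-bit-score hit (a protein retrieved by more
#' than one model is counted toward the model of higher significance;
#' exact ties go to the lexicographically first model name).
#'
#' @param proteins Protein tibble.
#' @param model_library List of [profile_hmm] objects (non-empty).
#' @param bit_cutoff Reporting cutoff (default 25, the moderate tier).
#' @param config An [rre_config].
#' @return Hit tibble.
#' @export
precision_scan <- function(proteins, model_library, bit_cutoff = 25,
                           config = rre_config()) {
  if (inherits(model_library, "profile_hmm")) model_library <- list(model_library)
  if (length(model_library) == 0) stop("model library is empty")
  hits <- scan_proteins(proteins, model_library, bit_cutoff = bit_cutoff,
                        config = config)
  mark_best_fit(hits)
}

mark_best_fit <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(best_fit = dplyr::row_number(
      order(-.data$bit_score, .data$model_name)) == 1L) |>
    dplyr::ungroup()
}

#' Excise an RRE region from a protein
#'
#' Cuts the hit envelope out of the parent protein, extended by `flank`
#' residues on each side and clipped to the protein bounds (envelope
#' 20-90 with flank 15 in a 200-residue protein gives region 5-105).
#' All coordinates are 1-based inclusive.
#'
#' @param protein Single-row protein tibble (the hit's parent).
#' @param hit Single-row hit tibble.
#' @param flank Non-negative flank width (0 = the envelope exactly; 15 is
#'   the width used when building the exploratory database).
#' @param origin Provenance label for the region.
#' @return One-row region tibble: `parent_id`, `model_name`,
#'   `region_from`, `region_to`, `flank_used`, `sequence`, `origin`,
#'   `env_from`, `env_to`.
#' @export
excise_rre <- function(protein, hit, flank = 0, origin = "precision") {
  if (flank < 0) stop("flank must be >= 0")
  p <- as_protein_row(protein)
  stopifnot(nrow(hit) == 1)
  if (!identical(hit$protein_id[[1]], p$id)) {
    stop("hit does not belong to protein '", p$id, "'")
  }
  len <- nchar(p$sequence)
  from <- max(1L, hit$env_from[[1]] - as.integer(flank))
  to <- min(len, hit$env_to[[1]] + as.integer(flank))
  tibble::tibble(
    parent_id = p$id,
    model_name = hit$model_name[[1]],
    region_from = from,
    region_to = to,
    flank_used = as.integer(flank),
    sequence = substr(p$sequence, from, to),
    origin = origin,
    env_from = hit$env_from[[1]],
    env_to = hit$env_to[[1]]
  )
}

#' Write excised regions as FASTA
#'
#' Headers record the parent id, model and 1-based region coordinates:
#' `"<parent>|<model>|<from>-<to>"`.
#'
#' @param regions Region tibble from [excise_rre()].
#' @param path Output path.
#' @export
write_regions_fasta <- function(regions, path) {
  write_fasta(tibble::tibble(
    id = sprintf("%s|%s|%d-%d", regions$parent_id, regions$model_name,
                 regions$region_from, regions$region_to),
    sequence = regions$sequence
  ), path)
}

#' Run the precision pipeline end to end
#'
#' Reads a FASTA proteome (or takes a protein tibble / [bgc_locus]),
#' scans it with the model library, optionally flags regulator hits,
#' excises the hit envelopes, and writes the hit TSV, the excised-region
#' FASTA and a JSON run-metadata sidecar (thresholds, seed, model
#' checksums).  Reruns with the same inputs are byte-identical.
#'
#' @param input FASTA path, protein tibble, or [bgc_locus].
#' @param model_library List of [profile_hmm] objects.
#' @param out_prefix Output path prefix (`<prefix>_hits.tsv`,
#'   `<prefix>_regions.fasta`, `<prefix>_meta.json`).
#' @param bit_cutoff Reporting cutoff.
#' @param flank Flank width for excision.
#' @param regulator_models Optional [RegulatorModelSet][regulator_model_set]
#'   used to set `regulator_flag`.
#' @param drop_flagged Drop regulator-flagged hits instead of only
#'   flagging them.
#' @param config An [rre_config].
#' @param seed Seed recorded in the metadata.
#' @return List with `hits`, `regions` and the output `paths`, invisibly.
#' @export
run_precision_pipeline <- function(input, model_library, out_prefix,
                                   bit_cutoff = 25, flank = 0,
                                   regulator_models = NULL,
                                   drop_flagged = FALSE,
                                   config = rre_config(), seed = 1) {
  proteins <- resolve_input(input)
  hits <- if (nrow(proteins) == 0) empty_hits() else {
    precision_scan(proteins, model_library, bit_cutoff = bit_cutoff,
                   config = config)
  }
  if (!is.null(regulator_models) && nrow(hits) > 0) {
    hits <- regulator_filter(hits, proteins, regulator_models)
    if (drop_flagged) hits <- dplyr::filter(hits, !.data$regulator_flag)
  }
  regions <- hits_to_regions(hits, proteins, flank = flank,
                             origin = "precision")
  paths <- write_pipeline_outputs(hits, regions, out_prefix,
                                  mode = "precision",
                                  models = model_library,
                                  config = config, seed = seed,
                                  bit_cutoff = bit_cutoff, flank = flank)
  invisible(list(hits = hits, regions = regions, paths = paths))
}

hits_to_regions <- function(hits, proteins, flank, origin) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      parent_id = character(0), model_name = character(0),
      region_from = integer(0), region_to = integer(0),
      flank_used = integer(0), sequence = character(0),
      origin = character(0), env_from = integer(0), env_to = integer(0)
    ))
  }
  purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    p <- proteins[proteins$id == hits$protein_id[[i]], , drop = FALSE]
    excise_rre(p, hits[i, ], flank = flank, origin = origin)
  })
}

resolve_input <- function(input) {
  if (is.character(input) && length(input) == 1) {
    if (grepl("\\.(gb|gbk|gbff|genbank)$", input, ignore.case = TRUE)) {
      loci <- read_genbank_locus(input)
      if (inherits(loci, "bgc_locus")) loci <- list(loci)
      return(purrr::map_dfr(loci, locus_proteins))
    }
    return(read_fasta(input))
  }
  if (inherits(input, "bgc_locus")) return(locus_proteins(input))
  tibble::as_tibble(input)
}

write_pipeline_outputs <- function(hits, regions, out_prefix, mode, models,
                                   config, seed, ...) {
  if (inherits(models, "profile_hmm")) models <- list(models)
  hits_path <- paste0(out_prefix, "_hits.tsv")
  fasta_path <- paste0(out_prefix, "_regions.fasta")
  meta_path <- paste0(out_prefix, "_meta.json")
  write_hits_tsv(hits, hits_path)
  write_regions_fasta(regions, fasta_path)
  checksums <- vapply(models, function(m) {
    sprintf("%s:M=%d:sum=%.6f", m$name, m$M, sum(m$match_emissions))
  }, character(1))
  meta <- list(
    tool = "rrescan", mode = mode, seed = seed,
    thresholds = unclass(config)[c("tier_bits", "min_align_len", "flank",
                                   "stage1_prob", "stage2_prob",
                                   "enrich_iterations", "enrich_evalue")],
    models = checksums,
    options = list(...)
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(hits = hits_path, regions = fasta_path, meta = meta_path)
}
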