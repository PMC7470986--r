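#' Threshold configuration for RRE detection
#'
#' Central registry of every numeric threshold used by the toolkit.  All
#' detection, excision, clustering and validation functions read their
#' cutoffs from this object rather than hard-coding them, so a single
#' edited config reproducibly retunes a whole run.
#'
#' The defaults are the operating points of the published RRE-detection
#' protocol: bit-score tiers of 15/25/35 (tolerant/moderate/stringent),
#' a minimum alignment length of 50 residues, 15 flanking residues around
#' excised domains, stage-1/stage-2 probability cutoffs of 0.40/0.90,
#' 80% identity for de-duplication clustering, RepNode conflation at
#' 60%/80% identity, SSN alignment-score thresholds of 22 and 25,
#' three enrichment iterations at E-value 0.05, a two-ORF co-occurrence
#' window, a 150-residue precursor length bound, 5-20 seed sequences per
#' model, and model acceptance at >95% recall (bit 25) with <100
#' cross-class hits.
#'
#' @param ... Named overrides for any default entry.
#' @return A list of class `rre_config`.
#' @examples
#' cfg <- rre_config(flank = 10)
#' cfg$tier_bits
#' @export
rre_config <- function(...) {
  cfg <- list(
    tier_bits = c(tolerant = 15, moderate = 25, stringent = 35),
    min_align_len = 50L,
    flank = 15L,
    stage1_prob = 0.40,
    stage2_prob = 0.90,
    cluster_identity = 0.80,
    repnode_identities = c(0.60, 0.80),
    ssn_alignment_scores = c(22, 25),
    enrich_iterations = 3L,
    enrich_evalue = 0.05,
    cooccur_orf_window = 2L,
    precursor_max_len = 150L,
    seed_count_range = c(5L, 20L),
    model_recall_min = 0.95,
    model_fp_max = 100L,
    excision_prob = 0.80,
    pseudocount = 1,
    calibrate_n = 200L,
    background = uniform_background()
  )
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) > 0) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "rre_config")
}

validate_config <- function(cfg) {
  tb <- cfg$tier_bits
  stopifnot(
    tb[["tolerant"]] < tb[["moderate"]],
    tb[["moderate"]] < tb[["stringent"]],
    cfg$stage1_prob >= 0, cfg$stage1_prob <= 1,
    cfg$stage2_prob >= 0, cfg$stage2_prob <= 1,
    cfg$excision_prob >= 0, cfg$excision_prob <= 1,
    cfg$cluster_identity > 0, cfg$cluster_identity <= 1,
    all(cfg$repnode_identities > 0), all(cfg$repnode_identities <= 1),
    cfg$flank >= 0,
    cfg$min_align_len >= 1,
    cfg$enrich_iterations >= 1,
    cfg$cooccur_orf_window >= 0,
    cfg$seed_count_range[1] <= cfg$seed_count_range[2]
  )
  invisible(cfg)
}

#' @export
print.rre_config <- function(x, ...) {
  cat("<rre_config>\n")
  cat("  tiers (bits):", paste(names(x$tier_bits), x$tier_bits,
                               sep = "=", collapse = " "), "\n")
  cat("  min_align_len:", x$min_align_len, " flank:", x$flank, "\n")
  cat("  stage probs:", x$stage1_prob, "/", x$stage2_prob,
      " cluster identity:", x$cluster_identity, "\n")
  invisible(x)
}

# Run code under a fixed RNG seed without touching the global stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
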