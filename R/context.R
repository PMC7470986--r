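#' Define a genomic co-occurrence rule
#'
#' A rule is satisfied when, for every partner set (outer AND), at least
#' one gene annotated with one of the set's domain-model names (inner OR)
#' lies within `max_orf_distance` open reading frames of the focal gene.
#' `max_orf_distance = Inf` means anywhere in the locus (the default for
#' the lasso-peptide peptidase + cyclase rule; radical-SAM rules use a
#' window of 2).
#'
#' @param rule_id Rule identifier.
#' @param required_partners List of character vectors of model names.
#' @param max_orf_distance ORF window (non-negative; `Inf` = whole locus).
#' @return Object of class `cooccurrence_rule`.
#' @export
cooccurrence_rule <- function(rule_id, required_partners,
                              max_orf_distance = Inf) {
  if (is.character(required_partners)) {
    required_partners <- list(required_partners)
  }
  stopifnot(length(required_partners) >= 1, max_orf_distance >= 0)
  structure(list(rule_id = rule_id, required_partners = required_partners,
                 max_orf_distance = max_orf_distance),
            class = "cooccurrence_rule")
}

#' Read co-occurrence rules from a JSON file
#'
#' Editable rule files carry entries
#' `{"rule_id": ..., "partners": [[...], ...], "max_orf_distance": ...}`;
#' a missing or `"anywhere"` distance means whole-locus.
#'
#' @param path JSON file path.
#' @return List of [cooccurrence_rule] objects.
#' @export
read_cooccurrence_rules <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) {
    d <- r$max_orf_distance
    d <- if (is.null(d) || identical(d, "anywhere")) Inf else as.numeric(d)
    cooccurrence_rule(r$rule_id,
                      lapply(r$partners, function(p) unlist(p)),
                      max_orf_distance = d)
  })
}

#' Annotate locus genes with domain models
#'
#' Each gene's annotation set becomes the names of library models scoring
#' at or above `bit_cutoff` on its translation.
#'
#' @param locus A [bgc_locus].
#' @param domain_library List of [profile_hmm] objects (may be empty).
#' @param bit_cutoff Annotation bit cutoff.
#' @param config An [rre_config].
#' @return The locus with `annotations` filled.
#' @export
annotate_locus <- function(locus, domain_library, bit_cutoff = 25,
                           config = rre_config()) {
  if (inherits(domain_library, "profile_hmm")) domain_library <- list(domain_library)
  locus$genes$annotations <- lapply(seq_len(nrow(locus$genes)), function(i) {
    s <- locus$genes$translation[[i]]
    hits <- vapply(domain_library, function(m) {
      r <- viterbi_raw(m, s)
      is.finite(r$score) && r$score >= bit_cutoff
    }, logical(1))
    vapply(domain_library[hits], `[[`, character(1), "name")
  })
  locus
}

#' Test a co-occurrence rule at a gene
#'
#' ORF distance is the difference of gene indices along the locus,
#' strand-blind; a rule with window 2 asks for a partner within two open
#' reading frames of the focal (RRE) gene.
#'
#' @param locus An annotated [bgc_locus].
#' @param rre_gene_index Focal gene index.
#' @param rule A [cooccurrence_rule].
#' @return `TRUE` iff every partner set is satisfied.
#' @export
check_cooccurrence <- function(locus, rre_gene_index, rule) {
  g <- locus$genes
  stopifnot(rre_gene_index %in% g$gene_index)
  dist <- abs(g$gene_index - rre_gene_index)
  all(vapply(rule$required_partners, function(partner_set) {
    any(vapply(seq_len(nrow(g)), function(i) {
      dist[i] <= rule$max_orf_distance &&
        length(intersect(g$annotations[[i]], partner_set)) > 0
    }, logical(1)))
  }, logical(1)))
}

#' Find precursor-peptide candidates near a gene
#'
#' Probable precursor peptides are small genes (translation strictly
#' shorter than `max_len`, default 150 residues) within `window` ORFs of
#' the RRE-containing gene, the gene itself excluded.
#'
#' @param locus A [bgc_locus].
#' @param rre_gene_index Focal gene index.
#' @param max_len Exclusive length bound (residues).
#' @param window ORF window.
#' @return Tibble of candidate genes (`gene_index`, `id`, `length`).
#' @export
find_precursor_candidates <- function(locus, rre_gene_index, max_len = 150,
                                      window = 3) {
  g <- locus$genes
  len <- nchar(g$translation)
  keep <- abs(g$gene_index - rre_gene_index) <= window &
    g$gene_index != rre_gene_index & len < max_len
  tibble::tibble(gene_index = g$gene_index[keep], id = g$id[keep],
                 length = len[keep])
}

#' Validate hits against labelled loci
#'
#' Computes, per bit-score tier, the number of hit proteins in positive
#' (RiPP) and negative (non-RiPP) loci, the number and fraction of
#' positive loci detected (>= 1 hit), and per-model counts of hits in
#' negative loci (false positives).  Hit protein ids must use the
#' `"<locus_id>|<gene_id>"` convention of [locus_proteins()].
#'
#' @param hits Hit tibble (tier thresholds are re-applied from the
#'   scores, so hits from a tolerant-cutoff scan give all three tiers).
#' @param positive_loci,negative_loci Lists of [bgc_locus] objects.
#' @param config An [rre_config].
#' @return Object of class `rre_validation`: a list with `per_tier` and
#'   `per_model` tibbles.
#' @export
validate_against_labeled_loci <- function(hits, positive_loci, negative_loci,
                                          config = rre_config()) {
  if (inherits(positive_loci, "bgc_locus")) positive_loci <- list(positive_loci)
  if (inherits(negative_loci, "bgc_locus")) negative_loci <- list(negative_loci)
  pos_ids <- vapply(positive_loci, `[[`, character(1), "locus_id")
  neg_ids <- vapply(negative_loci, `[[`, character(1), "locus_id")
  overlap <- intersect(pos_ids, neg_ids)
  if (length(overlap) > 0) {
    stop("locus ids appear in both labels: ", paste(overlap, collapse = ", "))
  }
  hit_locus <- sub("\\|.*$", "", hits$protein_id)
  per_tier <- purrr::map_dfr(names(config$tier_bits), function(tier) {
    cut <- config$tier_bits[[tier]]
    sel <- hits$bit_score >= cut
    loci_hit <- unique(hit_locus[sel])
    tibble::tibble(
      tier = tier, bit_cutoff = cut,
      hits_in_positive_loci = sum(sel & hit_locus %in% pos_ids),
      hits_in_negative_loci = sum(sel & hit_locus %in% neg_ids),
      positive_loci_detected = sum(pos_ids %in% loci_hit),
      recall = if (length(pos_ids) == 0) NA_real_ else
        sum(pos_ids %in% loci_hit) / length(pos_ids)
    )
  })
  per_model <- hits |>
    dplyr::mutate(locus = hit_locus,
                  label = dplyr::case_when(
                    .data$locus %in% pos_ids ~ "positive",
                    .data$locus %in% neg_ids ~ "negative",
                    TRUE ~ "unknown")) |>
    dplyr::group_by(.data$model_name) |>
    dplyr::summarise(
      hits = dplyr::n(),
      false_positives = sum(.data$label == "negative"),
      .groups = "drop"
    )
  structure(list(per_tier = per_tier, per_model = per_model,
                 n_positive_loci = length(pos_ids),
                 n_negative_loci = length(neg_ids)),
            class = "rre_validation")
}

#' @export
print.rre_validation <- function(x, ...) {
  cat("<rre_validation> ", x$n_positive_loci, " positive / ",
      x$n_negative_loci, " negative loci\n", sep = "")
  print(x$per_tier)
  invisible(x)
}

#' Model overlap matrix
#'
#' For a multi-model scan without best-fit de-duplication, entry (A, B)
#' counts the proteins hit by both models at the scan cutoff; the
#' diagonal holds per-model totals.  Overlap between models of closely
#' related classes measures model redundancy.
#'
#' @param hits Hit tibble.
#' @return Symmetric integer matrix with model names on both dimensions.
#' @export
model_overlap_matrix <- function(hits) {
  models <- sort(unique(hits$model_name))
  proteins <- unique(hits$protein_id)
  inc <- matrix(0L, nrow = length(proteins), ncol = length(models),
                dimnames = list(proteins, models))
  for (i in seq_len(nrow(hits))) {
    inc[hits$protein_id[[i]], hits$model_name[[i]]] <- 1L
  }
  crossprod(inc)
}

#' Model acceptance report
#'
#' The published acceptance rule for a class-specific model: recall of
#' labelled family positives at the moderate cutoff must exceed
#' `model_recall_min` (0.95, strict), and the number of cross-class hits
#' at the stringent cutoff must stay below `model_fp_max` (100, strict).
#'
#' @param model A [profile_hmm].
#' @param family_positives Protein tibble of true family members
#'   (non-empty).
#' @param cross_class_negatives Protein tibble of members of divergent
#'   classes.
#' @param config An [rre_config].
#' @return Tibble with `model`, `recall`, `n_positives`,
#'   `cross_class_hits`, `pass`.
#' @export
model_acceptance_report <- function(model, family_positives,
                                    cross_class_negatives,
                                    config = rre_config()) {
  if (nrow(family_positives) == 0) stop("empty positive set")
  moderate <- config$tier_bits[["moderate"]]
  stringent <- config$tier_bits[["stringent"]]
  pos_scores <- vapply(family_positives$sequence, function(s) {
    viterbi_raw(model, s)$score
  }, numeric(1), USE.NAMES = FALSE)
  recall <- mean(is.finite(pos_scores) & pos_scores >= moderate)
  fp <- if (nrow(cross_class_negatives) == 0) 0L else sum(vapply(
    cross_class_negatives$sequence, function(s) {
      r <- viterbi_raw(model, s)$score
      is.finite(r) && r >= stringent
    }, logical(1)))
  tibble::tibble(
    model = model$name,
    recall = recall,
    n_positives = nrow(family_positives),
    cross_class_hits = as.integer(fp),
    pass = recall > config$model_recall_min && fp < config$model_fp_max
  )
}
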