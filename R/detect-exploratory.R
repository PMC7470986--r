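#' Exploratory stage 1: profile-HMM prefilter and region extraction
#'
#' Every exploratory model is scored against every protein; hits at the
#' moderate bit cutoff with an alignment length of at least
#' `config$min_align_len` (50 residues) have their envelope excised with
#' `config$flank` (15) flanking residues on each side, one region per
#' (protein, model) best hit.
#'
#' @param proteins Protein tibble.
#' @param exploratory_models Non-empty list of [profile_hmm] objects.
#' @param config An [rre_config].
#' @return Region tibble (see [excise_rre()]) with an extra `stage1_bits`
#'   column.
#' @export
exploratory_stage1 <- function(proteins, exploratory_models,
                               config = rre_config()) {
  if (inherits(exploratory_models, "profile_hmm")) {
    exploratory_models <- list(exploratory_models)
  }
  stopifnot(length(exploratory_models) >= 1)
  cutoff <- config$tier_bits[["moderate"]]
  hits <- scan_proteins(proteins, exploratory_models, bit_cutoff = cutoff,
                        config = config)
  hits <- dplyr::filter(hits, .data$ali_len >= config$min_align_len)
  regions <- hits_to_regions(hits, proteins, flank = config$flank,
                             origin = "exploratory_stage1")
  if (nrow(regions) > 0) regions$stage1_bits <- hits$bit_score
  regions
}

#' Iterative profile enrichment
#'
#' An internal stand-in for iterative database expansion (PSI-BLAST /
#' HHblits style) that runs over a user-supplied companion sequence set:
#' round 1 seeds a single-sequence profile from the region; each round
#' calibrates the profile's E-values, admits companion sequences with
#' `E <= evalue_cutoff`, re-aligns the admitted sequences to the profile
#' along their Viterbi paths and rebuilds the profile.  Stops after
#' `iterations` rounds (default 3) or when no new sequence is admitted.
#'
#' @param region One-row region tibble (or anything with `sequence`; the
#'   id falls back to `parent_id` or `id`).
#' @param companion_db Protein tibble to enrich from (may have 0 rows).
#' @param iterations Maximum rounds.
#' @param evalue_cutoff Admission E-value cutoff (default 0.05).
#' @param config An [rre_config].
#' @param seed RNG seed (E-value calibration of intermediate profiles).
#' @return List with `alignment` (an [rre_alignment]), `profile`
#'   (a calibrated [profile_hmm]) and `admitted` (ids admitted from the
#'   companion set).
#' @export
iterative_enrich <- function(region, companion_db = NULL, iterations = 3,
                             evalue_cutoff = 0.05, config = rre_config(),
                             seed = 1) {
  seq0 <- region$sequence[[1]]
  id0 <- if ("parent_id" %in% names(region)) region$parent_id[[1]] else
    if ("id" %in% names(region)) region$id[[1]] else "seed"
  if (is.null(companion_db)) {
    companion_db <- tibble::tibble(id = character(0), sequence = character(0))
  }
  aln <- rre_alignment(id0, seq0)
  profile <- build_phmm(aln, name = paste0("enrich_", id0),
                        alpha = config$pseudocount,
                        background = config$background, allow_single = TRUE)
  admitted <- character(0)
  n_db <- max(1L, nrow(companion_db))
  for (round in seq_len(iterations)) {
    if (nrow(companion_db) == 0) break
    profile <- calibrate_evalue(profile, n_random = 100,
                                length_dist = function(n) {
                                  pmax(10L, stats::rpois(n, profile$M))
                                },
                                seed = seed + round)
    scores <- vapply(companion_db$sequence, function(s) {
      viterbi_raw(profile, s)$score
    }, numeric(1), USE.NAMES = FALSE)
    ev <- evalue_from_bits(profile, scores, n_db = n_db)
    new_admitted <- companion_db$id[is.finite(scores) & ev <= evalue_cutoff]
    if (setequal(new_admitted, admitted) && round > 1) break
    admitted <- new_admitted
    members <- companion_db[companion_db$id %in% admitted, , drop = FALSE]
    aln <- align_to_profile(profile, id0, seq0, members)
    profile <- build_phmm(aln, name = paste0("enrich_", id0),
                          alpha = config$pseudocount,
                          background = config$background, allow_single = TRUE)
  }
  if (is.na(profile$gumbel_mu)) {
    profile <- calibrate_evalue(profile, n_random = 100,
                                length_dist = function(n) {
                                  pmax(10L, stats::rpois(n, profile$M))
                                },
                                seed = seed)
  }
  list(alignment = aln, profile = profile, admitted = admitted)
}

# Align the seed plus a set of sequences onto a profile's match columns
# using their Viterbi paths; residues emitted by inserts are dropped.
align_to_profile <- function(profile, seed_id, seed_seq, members) {
  row_for <- function(s) {
    r <- viterbi_raw(profile, s)
    chars <- rep("-", profile$M)
    pos <- r$path
    take <- which(pos > 0)
    chars[take] <- substring(s, pos[take], pos[take])
    paste(chars, collapse = "")
  }
  ids <- c(seed_id, members$id)
  rows <- c(row_for(seed_seq),
            vapply(members$sequence, row_for, character(1), USE.NAMES = FALSE))
  rre_alignment(ids, rows)
}

#' Profile-profile local alignment
#'
#' Local alignment over the match columns of two profiles with the
#' co-emission log-odds column score
#' `S(i, j) = log2(sum_a p_i(a) * q_j(a) / f_a)` and affine column-gap
#' penalties (open 3 bits, extend 0.3 bits).  Pure-background columns
#' score at most 0, so unrelated profiles produce no positive local
#' alignment.
#'
#' @param query_profile,reference_profile [profile_hmm] objects.
#' @param gap_open,gap_extend Gap costs in bits.
#' @return List with `score` (bits) and `aligned_len` (columns on the
#'   optimal local path, gaps included).
#' @export
profile_profile_align <- function(query_profile, reference_profile,
                                  gap_open = 3, gap_extend = 0.3) {
  P <- query_profile$match_emissions
  Q <- reference_profile$match_emissions
  f <- query_profile$background
  S <- log2(P %*% (t(Q) / rep(f, each = nrow(Q))))
  # guard: columns with disjoint support give -Inf; score them harshly
  S[!is.finite(S)] <- -1000
  res <- sw_affine_cpp(S, gap_open, gap_extend)
  list(score = res$score, aligned_len = res$aligned_len,
       aligned_pairs = res$aligned_pairs)
}

#' Calibrate the stage-2 confirmation probability
#'
#' The published confirmation step thresholds an HHsearch probability;
#' that probability model is not reproducible from its description, so
#' the package uses a documented surrogate: a logistic regression of
#' synthetic positive/negative labels on the profile-profile alignment
#' score and aligned length.  Positives are sequences sampled from the
#' reference generator profiles and enriched against a sampled companion
#' pool; negatives are background decoys put through the same machinery.
#' Under clean separation (the common case for synthetic training sets)
#' the fit falls back to a steep logistic centred on the midpoint between
#' the best negative and worst positive score, with a message.
#'
#' @param reference_profiles List of reference [profile_hmm] objects
#'   (stand-ins for the RRE structure references).
#' @param n_pos,n_neg Numbers of synthetic positives/negatives (>= 100).
#' @param seed RNG seed; coefficients are deterministic given the seed.
#' @param config An [rre_config].
#' @param pool_size Companion-pool size sampled per reference.
#' @return Object of class `stage2_calibration` with elements `beta0`,
#'   `beta_score`, `beta_len`, `method`, `training`.
#' @export
calibrate_stage2 <- function(reference_profiles, n_pos = 100, n_neg = 100,
                             seed = 1, config = rre_config(),
                             pool_size = 25) {
  stopifnot(n_pos >= 100, n_neg >= 100)
  if (inherits(reference_profiles, "profile_hmm")) {
    reference_profiles <- list(reference_profiles)
  }
  nref <- length(reference_profiles)
  pools <- lapply(seq_len(nref), function(r) {
    sample_from_phmm(reference_profiles[[r]], pool_size, seed = seed + 1000 + r,
                     prefix = sprintf("pool%d_", r))
  })
  mean_M <- round(mean(vapply(reference_profiles, `[[`, numeric(1), "M")))

  feature_of <- function(seqs, pool, seed_off) {
    purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
      enr <- iterative_enrich(
        tibble::tibble(id = seqs$id[[i]], sequence = seqs$sequence[[i]]),
        companion_db = pool, iterations = config$enrich_iterations,
        evalue_cutoff = config$enrich_evalue, config = config,
        seed = seed + seed_off + i
      )
      best <- best_reference_alignment(enr$profile, reference_profiles)
      tibble::tibble(score = best$score, aligned_len = best$aligned_len)
    })
  }

  per_ref <- ceiling(n_pos / nref)
  pos_feats <- purrr::map_dfr(seq_len(nref), function(r) {
    seqs <- sample_from_phmm(reference_profiles[[r]], per_ref,
                             seed = seed + 2000 + r,
                             prefix = sprintf("pos%d_", r))
    feature_of(seqs, pools[[r]], seed_off = 3000 + r * per_ref)
  })[seq_len(n_pos), , drop = FALSE]

  decoys <- make_decoys(n_neg, length_dist = function(n) {
    pmax(60L, stats::rpois(n, mean_M + 2 * config$flank))
  }, background = config$background, seed = seed + 4000, prefix = "neg")
  all_pool <- dplyr::bind_rows(pools)
  neg_feats <- feature_of(decoys, all_pool, seed_off = 5000)

  feats <- dplyr::bind_rows(
    dplyr::mutate(pos_feats, label = 1L),
    dplyr::mutate(neg_feats, label = 0L)
  )
  fit_stage2_logistic(feats)
}

best_reference_alignment <- function(profile, reference_profiles) {
  alns <- lapply(reference_profiles, function(ref) {
    profile_profile_align(profile, ref)
  })
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- which.max(scores)
  list(score = alns[[best]]$score, aligned_len = alns[[best]]$aligned_len,
       reference = best)
}

fit_stage2_logistic <- function(feats) {
  fit <- suppressWarnings(
    stats::glm(label ~ score + aligned_len, family = stats::binomial(),
               data = feats, control = stats::glm.control(epsilon = 1e-8,
                                                          maxit = 100))
  )
  co <- stats::coef(fit)
  separated <- !fit$converged || any(is.na(co)) ||
    any(abs(co[c("score", "aligned_len")]) > 15) || co[["score"]] <= 0
  if (!separated) {
    calib <- list(beta0 = unname(co[1]), beta_score = unname(co[["score"]]),
                  beta_len = unname(co[["aligned_len"]]), method = "logistic")
  } else {
    pos <- feats$score[feats$label == 1]
    neg <- feats$score[feats$label == 0]
    min_pos <- min(pos); max_neg <- max(neg)
    mid <- (min_pos + max_neg) / 2
    margin <- max((min_pos - mid), 1e-3)
    beta_score <- 10 / margin
    message("stage-2 calibration: perfect separation; using margin-based ",
            "threshold at score ", signif(mid, 4))
    calib <- list(beta0 = -beta_score * mid, beta_score = beta_score,
                  beta_len = 0, method = "margin")
  }
  calib$training <- dplyr::summarise(
    dplyr::group_by(feats, .data$label),
    n = dplyr::n(), mean_score = mean(.data$score),
    mean_len = mean(.data$aligned_len), .groups = "drop"
  )
  structure(calib, class = "stage2_calibration")
}

#' @export
print.stage2_calibration <- function(x, ...) {
  cat("<stage2_calibration> method=", x$method,
      " beta=(", signif(x$beta0, 4), ", ", signif(x$beta_score, 4),
      ", ", signif(x$beta_len, 4), ")\n", sep = "")
  invisible(x)
}

#' Stage-2 confirmation probability
#'
#' @param calibration A [calibrate_stage2()] result.
#' @param score Profile-profile score (bits).
#' @param aligned_len Aligned columns.
#' @return Probability in `[0, 1]`, strictly increasing in `score`.
#' @export
stage2_probability <- function(calibration, score, aligned_len) {
  stopifnot(inherits(calibration, "stage2_calibration"))
  stats::plogis(calibration$beta0 + calibration$beta_score * score +
                  calibration$beta_len * aligned_len)
}

#' Exploratory stage 2: profile-profile confirmation
#'
#' Each stage-1 candidate region is enriched into a profile
#' ([iterative_enrich()]) and aligned against every reference profile;
#' the best alignment's calibrated probability confirms the candidate
#' when it reaches `config$stage2_prob` (0.90) with at least
#' `config$min_align_len` (50) aligned columns.
#'
#' @param candidates Region tibble from [exploratory_stage1()].
#' @param reference_profiles List of reference [profile_hmm] objects.
#' @param config An [rre_config].
#' @param calibration A fitted [calibrate_stage2()] object (required).
#' @param companion_db Protein tibble used for enrichment (may be empty).
#' @param seed RNG seed.
#' @return The candidate tibble with `stage2_score`,
#'   `stage2_aligned_len`, `stage2_prob`, `best_reference` and
#'   `confirmed` columns.
#' @export
exploratory_stage2 <- function(candidates, reference_profiles,
                               config = rre_config(), calibration,
                               companion_db = NULL, seed = 1) {
  if (missing(calibration) || !inherits(calibration, "stage2_calibration")) {
    stop("exploratory stage 2 requires a fitted stage2_calibration ",
         "(see calibrate_stage2())", call. = FALSE)
  }
  if (inherits(reference_profiles, "profile_hmm")) {
    reference_profiles <- list(reference_profiles)
  }
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, stage2_score = numeric(0),
                         stage2_aligned_len = integer(0),
                         stage2_prob = numeric(0),
                         best_reference = integer(0),
                         confirmed = logical(0)))
  }
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    enr <- iterative_enrich(candidates[i, ], companion_db = companion_db,
                            iterations = config$enrich_iterations,
                            evalue_cutoff = config$enrich_evalue,
                            config = config, seed = seed + i)
    best <- best_reference_alignment(enr$profile, reference_profiles)
    prob <- stage2_probability(calibration, best$score, best$aligned_len)
    tibble::tibble(
      stage2_score = best$score,
      stage2_aligned_len = as.integer(best$aligned_len),
      stage2_prob = prob,
      best_reference = as.integer(best$reference),
      confirmed = prob >= config$stage2_prob &&
        best$aligned_len >= config$min_align_len
    )
  })
  out <- dplyr::bind_cols(candidates, res)
  # hard invariant: a confirmed candidate satisfies both conditions
  stopifnot(all(!out$confirmed |
                  (out$stage2_prob >= config$stage2_prob &
                     out$stage2_aligned_len >= config$min_align_len)))
  out
}

#' Run the exploratory pipeline end to end
#'
#' Stage-1 prefilter and extraction, stage-2 enrichment and
#' profile-profile confirmation, optional regulator flagging, then the
#' standard outputs (hit TSV for confirmed candidates, excised-region
#' FASTA, JSON metadata).  When precision-mode hits are supplied, the
#' output marks which exploratory hits overlap them.
#'
#' @inheritParams run_precision_pipeline
#' @param exploratory_models Stage-1 model list.
#' @param reference_profiles Stage-2 reference profiles.
#' @param companion_db Enrichment sequence set (protein tibble or FASTA
#'   path; may be `NULL`).
#' @param calibration A [calibrate_stage2()] object.
#' @param precision_hits Optional hit tibble from
#'   [run_precision_pipeline()] for overlap marking.
#' @return List with `candidates` (all stage-1 regions with stage-2
#'   columns), `hits` (confirmed, as a hit table), `paths`.
#' @export
run_exploratory_pipeline <- function(input, exploratory_models,
                                     reference_profiles, companion_db,
                                     out_prefix, calibration,
                                     regulator_models = NULL,
                                     drop_flagged = FALSE,
                                     precision_hits = NULL,
                                     config = rre_config(), seed = 1) {
  proteins <- resolve_input(input)
  if (is.character(companion_db)) companion_db <- read_fasta(companion_db)
  cands <- if (nrow(proteins) == 0) {
    hits_to_regions(empty_hits(), proteins, flank = config$flank,
                    origin = "exploratory_stage1")
  } else {
    exploratory_stage1(proteins, exploratory_models, config = config)
  }
  cands <- exploratory_stage2(cands, reference_profiles, config = config,
                              calibration = calibration,
                              companion_db = companion_db, seed = seed)
  confirmed <- dplyr::filter(cands, .data$confirmed)
  hits <- if (nrow(confirmed) == 0) empty_hits() else tibble::tibble(
    protein_id = confirmed$parent_id,
    model_name = confirmed$model_name,
    bit_score = confirmed$stage1_bits,
    evalue = NA_real_,
    env_from = confirmed$env_from,
    env_to = confirmed$env_to,
    ali_len = confirmed$env_to - confirmed$env_from + 1L,
    tiers = lapply(confirmed$stage1_bits, assign_tiers, config = config),
    best_fit = FALSE,
    regulator_flag = FALSE
  )
  hits <- mark_best_fit(hits)
  if (!is.null(regulator_models) && nrow(hits) > 0) {
    hits <- regulator_filter(hits, proteins, regulator_models)
    if (drop_flagged) hits <- dplyr::filter(hits, !.data$regulator_flag)
  }
  if (!is.null(precision_hits) && nrow(hits) > 0) {
    hits$overlaps_precision <- vapply(seq_len(nrow(hits)), function(i) {
      ph <- precision_hits[precision_hits$protein_id == hits$protein_id[[i]], ,
                           drop = FALSE]
      nrow(ph) > 0 && any(pmin(ph$env_to, hits$env_to[[i]]) -
                            pmax(ph$env_from, hits$env_from[[i]]) >= 0)
    }, logical(1))
  }
  regions <- dplyr::select(confirmed, dplyr::any_of(c(
    "parent_id", "model_name", "region_from", "region_to", "flank_used",
    "sequence", "origin", "env_from", "env_to"
  )))
  paths <- write_pipeline_outputs(hits, regions, out_prefix,
                                  mode = "exploratory",
                                  models = exploratory_models,
                                  config = config, seed = seed)
  invisible(list(candidates = cands, hits = hits, paths = paths))
}
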