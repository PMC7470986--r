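# shared fixture: one RRE-like family and its detection model
fam_det <- make_family(m = 70, n_members = 30, divergence = 0.35, seed = 110,
                       name = "rreA", class_tag = "classA")
mod_det <- family_model(fam_det, n_seed = 15, name = "rreA",
                        class_tag = "classA")

test_that("tier assignment follows the published 15/25/35 cutoffs", {
  cfg <- rre_config()
  expect_setequal(assign_tiers(40, cfg), c("tolerant", "moderate", "stringent"))
  expect_setequal(assign_tiers(20, cfg), "tolerant")
  expect_equal(length(assign_tiers(14.99, cfg)), 0)
  expect_setequal(assign_tiers(15, cfg), "tolerant")
  expect_setequal(assign_tiers(35, cfg), c("tolerant", "moderate", "stringent"))
})

test_that("precision scan marks best_fit on the highest-scoring model", {
  # a second, weaker model for the same family: fewer seeds, higher alpha
  weak <- build_phmm(rre_alignment(fam_det$msa$rows$id[16:20],
                                   fam_det$msa$rows$aligned[16:20]),
                     name = "rreB", alpha = 5)
  proteome <- fam_det$members[21:26, c("id", "description", "sequence")]
  hits <- precision_scan(proteome, list(weak, mod_det), bit_cutoff = 15)
  both <- hits |>
    dplyr::count(protein_id) |>
    dplyr::filter(n == 2) |>
    dplyr::pull(protein_id)
  expect_gt(length(both), 0)
  for (pid in both) {
    h <- hits[hits$protein_id == pid, ]
    expect_equal(h$best_fit, h$bit_score == max(h$bit_score))
  }
  expect_error(precision_scan(proteome, list()), "empty")
})

test_that("exact best-fit ties go to the lexicographically first model", {
  m1 <- mod_det; m1$name <- "model_b"
  m2 <- mod_det; m2$name <- "model_a"   # identical scores guaranteed
  proteome <- fam_det$members[27:28, c("id", "description", "sequence")]
  hits <- precision_scan(proteome, list(m1, m2), bit_cutoff = 15)
  for (pid in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pid, ]
    expect_equal(h$model_name[h$best_fit], "model_a")
  }
})

test_that("excision arithmetic extends, clips, and validates", {
  prot <- tibble::tibble(id = "p", description = "", sequence = strrep("A", 200))
  hit <- tibble::tibble(protein_id = "p", model_name = "m", bit_score = 50,
                        evalue = NA_real_, env_from = 20L, env_to = 90L,
                        ali_len = 71L, tiers = list("tolerant"),
                        best_fit = TRUE, regulator_flag = FALSE)
  r <- excise_rre(prot, hit, flank = 15)
  expect_equal(c(r$region_from, r$region_to), c(5L, 105L))
  expect_equal(nchar(r$sequence), 101)

  hit2 <- dplyr::mutate(hit, env_from = 5L, env_to = 60L)
  r2 <- excise_rre(prot, hit2, flank = 15)
  expect_equal(c(r2$region_from, r2$region_to), c(1L, 75L))

  r0 <- excise_rre(prot, hit, flank = 0)
  expect_equal(c(r0$region_from, r0$region_to), c(20L, 90L))
  expect_equal(nchar(r0$sequence), 71)

  expect_error(excise_rre(prot, hit, flank = -1), ">= 0")
  expect_error(excise_rre(dplyr::mutate(prot, id = "other"), hit),
               "does not belong")
})

test_that("re-scanning an excised envelope reproduces the original score", {
  proteome <- fam_det$members[21:30, c("id", "description", "sequence")]
  hits <- precision_scan(proteome, mod_det, bit_cutoff = 15)
  expect_gt(nrow(hits), 5)
  for (i in seq_len(nrow(hits))) {
    p <- proteome[proteome$id == hits$protein_id[[i]], ]
    r <- excise_rre(p, hits[i, ], flank = 0)
    rescan <- score_viterbi(mod_det, list(id = "r", sequence = r$sequence))
    expect_lt(abs(rescan$bit_score - hits$bit_score[[i]]), 1)
  }
})

test_that("stage 1 enforces the moderate cutoff and 50-residue length", {
  short_fam <- make_family(m = 40, n_members = 25, divergence = 0.3,
                           seed = 111, name = "shortdom")
  short_mod <- family_model(short_fam, n_seed = 10, name = "shortdom")
  cfg <- rre_config()
  # short-domain hits have ali_len ~ 40 < 50 -> rejected even at high bits
  proteome_short <- short_fam$members[11:16, c("id", "description", "sequence")]
  expect_equal(nrow(exploratory_stage1(proteome_short, short_mod, cfg)), 0)
  # long-domain hits pass and come back with 15-residue flanks
  proteome_long <- fam_det$members[21:24, c("id", "description", "sequence")]
  regs <- exploratory_stage1(proteome_long, mod_det, cfg)
  expect_equal(nrow(regs), 4)
  expect_true(all(regs$flank_used == 15))
  expect_true(all(regs$stage1_bits >= cfg$tier_bits[["moderate"]]))
  expect_true(all(regs$region_from <= regs$env_from))
  expect_true(all(regs$region_to >= regs$env_to))
})

test_that("regulator filtering flags overlap above trusted cutoffs only", {
  hth <- make_hth_decoys(4, seed = 112)
  proteome <- dplyr::bind_rows(
    hth$proteins,
    fam_det$members[21:24, c("id", "description", "sequence")]
  )
  # detect with both an RRE model and the HTH model acting as bait
  hits <- scan_proteins(proteome, list(mod_det, hth$model), bit_cutoff = 15)
  flagged <- regulator_filter(hits, proteome, hth$regulator_set)
  hth_ids <- hth$proteins$id
  expect_true(all(flagged$regulator_flag[flagged$protein_id %in% hth_ids]))
  expect_false(any(flagged$regulator_flag[!flagged$protein_id %in% hth_ids]))

  # below the trusted cutoff: nothing flagged
  strict <- hth$regulator_set
  strict$models[[1]]$trusted_cutoff <- 1e6
  unflagged <- regulator_filter(hits, proteome, strict)
  expect_false(any(unflagged$regulator_flag))

  # no envelope overlap: regulator at the N terminus, hit at the C terminus
  reg_prot <- tibble::tibble(
    id = "chimera", description = "",
    sequence = paste0(hth$proteins$sequence[[1]], strrep("A", 150))
  )
  fake_hit <- tibble::tibble(
    protein_id = "chimera", model_name = "rreA", bit_score = 40,
    evalue = NA_real_,
    env_from = nchar(reg_prot$sequence) - 30L,
    env_to = nchar(reg_prot$sequence) - 1L,
    ali_len = 30L, tiers = list("tolerant"), best_fit = TRUE,
    regulator_flag = FALSE
  )
  res <- regulator_filter(fake_hit, reg_prot, hth$regulator_set)
  expect_false(res$regulator_flag)

  # models without a trusted cutoff are refused
  nocut <- hth$model; nocut$trusted_cutoff <- NA_real_
  expect_error(regulator_model_set(list(nocut)), "trusted_cutoff")
})

test_that("the precision pipeline writes deterministic, complete outputs", {
  dir <- withr::local_tempdir()
  proteome <- dplyr::bind_rows(
    fam_det$members[21:23, c("id", "description", "sequence")],
    make_decoys(3, seed = 113)
  )
  pre1 <- file.path(dir, "run1")
  pre2 <- file.path(dir, "run2")
  r1 <- run_precision_pipeline(proteome, mod_det, pre1, flank = 15, seed = 7)
  r2 <- run_precision_pipeline(proteome, mod_det, pre2, flank = 15, seed = 7)
  expect_identical(readLines(paste0(pre1, "_hits.tsv")),
                   readLines(paste0(pre2, "_hits.tsv")))
  expect_equal(nrow(r1$hits), 3)
  expect_true(file.exists(paste0(pre1, "_regions.fasta")))
  meta <- jsonlite::read_json(paste0(pre1, "_meta.json"))
  expect_equal(meta$mode, "precision")
  expect_equal(meta$seed, 7)

  # empty input -> header-only outputs, no error
  empty_fa <- file.path(dir, "empty.fasta")
  file.create(empty_fa)
  r0 <- run_precision_pipeline(tibble::tibble(id = character(0),
                                              description = character(0),
                                              sequence = character(0)),
                               mod_det, file.path(dir, "empty"))
  expect_equal(nrow(r0$hits), 0)
  expect_length(readLines(file.path(dir, "empty_hits.tsv")), 1)
})

test_that("GenBank input feeds the pipeline through locus protein ids", {
  tl <- make_toy_locus(c("precursor", "rre", "rsam"), seed = 114)
  dir <- withr::local_tempdir()
  gbk <- file.path(dir, "locus.gbk")
  write_genbank_locus(tl$locus, gbk)
  res <- run_precision_pipeline(gbk, tl$models$rre, file.path(dir, "gb"),
                                bit_cutoff = 25)
  expect_equal(nrow(res$hits), 1)
  expect_match(res$hits$protein_id, "^toy_locus\\|g02_rre$")
})
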