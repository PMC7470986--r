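# shared fixture: a reference family with a companion pool
fam_exp <- make_family(m = 80, n_members = 40, divergence = 0.3, seed = 120,
                       name = "refX")
ref_exp <- family_model(fam_exp, n_seed = 15, name = "refX")
pool_exp <- fam_exp$members[16:35, c("id", "sequence")]

test_that("enrichment from an empty companion set is a fixed point", {
  region <- tibble::tibble(id = "solo", sequence = fam_exp$members$sequence[[36]])
  enr <- iterative_enrich(region, companion_db = NULL, seed = 3)
  expect_equal(nrow(enr$alignment$rows), 1)
  expect_length(enr$admitted, 0)
  expect_equal(enr$profile$M, nchar(region$sequence))
  # a second pass changes nothing
  enr2 <- iterative_enrich(region, companion_db = tibble::tibble(
    id = character(0), sequence = character(0)), seed = 3)
  expect_equal(enr2$profile$match_emissions, enr$profile$match_emissions)
})

test_that("exact copies are admitted in the first round", {
  seqs <- fam_exp$members$sequence[[37]]
  db <- tibble::tibble(id = sprintf("copy%d", 1:5), sequence = rep(seqs, 5))
  enr <- iterative_enrich(tibble::tibble(id = "q", sequence = seqs), db,
                          seed = 4)
  expect_setequal(enr$admitted, db$id)
  expect_equal(nrow(enr$alignment$rows), 6)
})

test_that("enrichment recovers planted homologs and rejects decoys", {
  q <- sample_from_phmm(fam_exp$generator, 1, seed = 121)
  homologs <- sample_from_phmm(fam_exp$generator, 10, seed = 122,
                               prefix = "hom")
  decoys <- make_decoys(100, length_dist = function(n) {
    pmax(40L, stats::rpois(n, 80))
  }, seed = 123)
  db <- dplyr::bind_rows(homologs[, c("id", "sequence")],
                         decoys[, c("id", "sequence")])
  enr <- iterative_enrich(tibble::tibble(id = "q", sequence = q$sequence),
                          db, iterations = 3, seed = 5)
  expect_gte(sum(grepl("^hom", enr$admitted)), 8)
  expect_equal(sum(grepl("^decoy", enr$admitted)), 0)
  # determinism
  enr2 <- iterative_enrich(tibble::tibble(id = "q", sequence = q$sequence),
                           db, iterations = 3, seed = 5)
  expect_identical(enr$admitted, enr2$admitted)
  expect_equal(enr$profile$match_emissions, enr2$profile$match_emissions)
})

test_that("profile-profile alignment obeys its closed forms and an oracle", {
  pm <- point_mass_hmm("ACDEF")
  self <- profile_profile_align(pm, pm)
  expect_equal(self$score, 5 * log2(20), tolerance = 1e-9)
  expect_equal(self$aligned_len, 5)

  # pure-background columns can never build a positive local alignment
  emis <- matrix(1 / 20, 6, 20)
  trans <- matrix(rep(c(1, 0, 0, 1, 0, 1, 0), each = 6), nrow = 6)
  flat <- profile_hmm("flat", emis, trans)
  expect_equal(profile_profile_align(flat, ref_exp)$score, 0)

  # exhaustive enumeration for small profiles
  for (k in 1:5) {
    q <- random_3letter_hmm(sample(2:4, 1), seed = 130 + k)
    r <- random_3letter_hmm(sample(2:4, 1), seed = 140 + k)
    S <- log2(q$match_emissions %*%
                (t(r$match_emissions) / rep(q$background, each = r$M)))
    S[!is.finite(S)] <- -1000
    got <- profile_profile_align(q, r)
    expect_equal(got$score, enum_pp_score(S), tolerance = 1e-9)
  }
})

test_that("the stage-2 probability model behaves and fails over correctly", {
  # overlapping classes -> a genuine logistic fit with positive score slope
  feats <- withr::with_seed(150, tibble::tibble(
    score = c(rnorm(150, 30, 10), rnorm(150, 60, 10)),
    aligned_len = round(c(rnorm(150, 60, 5), rnorm(150, 70, 5))),
    label = rep(0:1, each = 150)
  ))
  cal <- rrescan:::fit_stage2_logistic(feats)
  expect_equal(cal$method, "logistic")
  expect_gt(cal$beta_score, 0)
  p1 <- stage2_probability(cal, 40, 65)
  p2 <- stage2_probability(cal, 60, 65)
  expect_gt(p2, p1)

  # cleanly separated classes -> margin fallback, midpoint threshold
  feats2 <- tibble::tibble(
    score = c(seq(5, 20, length.out = 120), seq(200, 300, length.out = 120)),
    aligned_len = 70,
    label = rep(0:1, each = 120)
  )
  expect_message(cal2 <- rrescan:::fit_stage2_logistic(feats2), "separation")
  expect_equal(cal2$method, "margin")
  expect_lt(stage2_probability(cal2, 20, 70), 0.5)
  expect_gt(stage2_probability(cal2, 200, 70), 0.99)
  # monotone in score
  probs <- stage2_probability(cal2, seq(0, 300, by = 10), 70)
  expect_true(all(diff(probs) >= 0))
})

test_that("stage 2 confirms on probability AND length, never on one alone", {
  cal <- structure(list(beta0 = -10, beta_score = 0.5, beta_len = 0,
                        method = "margin", training = NULL),
                   class = "stage2_calibration")
  cfg <- rre_config()
  proteome <- fam_exp$members[36:38, c("id", "description", "sequence")]
  cands <- exploratory_stage1(proteome, ref_exp, cfg)
  expect_gt(nrow(cands), 0)
  out <- exploratory_stage2(cands, ref_exp, cfg, calibration = cal,
                            companion_db = pool_exp, seed = 8)
  expect_true(all(out$confirmed ==
                    (out$stage2_prob >= cfg$stage2_prob &
                       out$stage2_aligned_len >= cfg$min_align_len)))
  expect_true(all(out$confirmed))   # planted members confirm

  # a high probability with a short alignment must not confirm: shrink the
  # length requirement into impossibility via config
  cfg_long <- rre_config(min_align_len = 2000L)
  out2 <- exploratory_stage2(cands[1, ], ref_exp, cfg_long, calibration = cal,
                             companion_db = pool_exp, seed = 8)
  expect_false(any(out2$confirmed))
  expect_gt(out2$stage2_prob[1], 0.9)

  expect_error(exploratory_stage2(cands, ref_exp, cfg, calibration = NULL),
               "calibration")
})
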