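# shared generators so the same families appear across loci
gens_ctx <- local({
  tl <- make_toy_locus(c("rre"), seed = 200)
  tl$generators
})

toy_ctx <- function(plan, seed) {
  make_toy_locus(plan, seed = seed, locus_id = sprintf("L%d", seed),
                 generators = gens_ctx)
}

test_that("locus annotation matches planted gene roles and nests by cutoff", {
  tl <- toy_ctx(c("precursor", "rre", "rsam", "random"), seed = 201)
  lib <- unname(tl$models)
  loc25 <- annotate_locus(tl$locus, lib, bit_cutoff = 25)
  ann <- loc25$genes$annotations
  expect_equal(ann[[2]], "rre_fam")
  expect_equal(ann[[3]], "rSAM")
  expect_length(ann[[1]], 0)
  expect_length(ann[[4]], 0)

  loc35 <- annotate_locus(tl$locus, lib, bit_cutoff = 35)
  loc15 <- annotate_locus(tl$locus, lib, bit_cutoff = 15)
  for (i in seq_along(ann)) {
    expect_true(all(loc35$genes$annotations[[i]] %in%
                      loc25$genes$annotations[[i]]))
    expect_true(all(loc25$genes$annotations[[i]] %in%
                      loc15$genes$annotations[[i]]))
  }
  empty <- annotate_locus(tl$locus, list(), bit_cutoff = 25)
  expect_true(all(lengths(empty$genes$annotations) == 0))
})

test_that("ORF-window co-occurrence matches constructed truth", {
  rule2 <- cooccurrence_rule("rsam_win2", list("rSAM"), max_orf_distance = 2)
  tl_near <- toy_ctx(c("precursor", "rre", "rsam"), seed = 202)
  near <- annotate_locus(tl_near$locus, unname(tl_near$models), 25)
  expect_true(check_cooccurrence(near, 2, rule2))

  tl_far <- toy_ctx(c("rre", "random", "random", "rsam"), seed = 203)
  far <- annotate_locus(tl_far$locus, unname(tl_far$models), 25)
  expect_false(check_cooccurrence(far, 1, rule2))   # distance 3 > 2
  rule3 <- cooccurrence_rule("rsam_win3", list("rSAM"), max_orf_distance = 3)
  expect_true(check_cooccurrence(far, 1, rule3))    # boundary: distance == 3

  # reversing the gene order preserves all ORF distances
  rev_genes <- far$genes[rev(seq_len(nrow(far$genes))), ]
  rev_genes$start <- seq_len(nrow(rev_genes))
  rev_locus <- bgc_locus("rev", rev_genes)
  rev_locus <- annotate_locus(rev_locus, unname(tl_far$models), 25)
  expect_false(check_cooccurrence(rev_locus, 4, rule2))
  expect_true(check_cooccurrence(rev_locus, 4, rule3))
})

test_that("AND rules need every partner set satisfied", {
  # build an annotated locus by hand: peptidase at gene 1, cyclase at 3
  genes <- tibble::tibble(
    id = c("g1", "g2", "g3"), strand = "+",
    translation = c(strrep("MK", 40), strrep("AV", 40), strrep("LD", 40)),
    annotations = list("peptidase", character(0), "cyclase")
  )
  loc <- bgc_locus("lasso1", genes)
  rule <- cooccurrence_rule("lasso", list("peptidase", "cyclase"),
                            max_orf_distance = Inf)
  expect_true(check_cooccurrence(loc, 2, rule))
  loc$genes$annotations[[3]] <- character(0)   # lose the cyclase
  expect_false(check_cooccurrence(loc, 2, rule))
  # OR within a partner set
  rule_or <- cooccurrence_rule("lasso_or",
                               list(c("peptidase", "cyclase")), Inf)
  expect_true(check_cooccurrence(loc, 2, rule_or))
})

test_that("co-occurrence rules round-trip through JSON config", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(rule_id = "rsam_win2", partners = list(list("rSAM")),
         max_orf_distance = 2),
    list(rule_id = "lasso", partners = list(list("peptidase"), list("cyclase")),
         max_orf_distance = "anywhere")
  ), path, auto_unbox = TRUE)
  rules <- read_cooccurrence_rules(path)
  expect_length(rules, 2)
  expect_equal(rules[[1]]$max_orf_distance, 2)
  expect_equal(rules[[2]]$max_orf_distance, Inf)
  expect_length(rules[[2]]$required_partners, 2)
})

test_that("precursor candidates respect the strict length bound and window", {
  genes <- tibble::tibble(
    id = sprintf("g%d", 1:6), strand = "+",
    translation = c(strrep("A", 90),    # candidate
                    strrep("A", 150),   # boundary: excluded (strict <)
                    strrep("A", 300),   # rre host, focal gene
                    strrep("A", 149),   # candidate
                    strrep("A", 80),    # within window 3
                    strrep("A", 70)),   # outside window 3
    annotations = list(character(0), character(0), "rre", character(0),
                       character(0), character(0))
  )
  # place the small gene 5 ORFs away by padding indexes: use explicit starts
  genes$start <- c(10, 20, 30, 40, 50, 90)
  loc <- bgc_locus("prec", genes)
  cand <- find_precursor_candidates(loc, rre_gene_index = 3, max_len = 150,
                                    window = 3)
  expect_setequal(cand$id, c("g1", "g4", "g5", "g6"))
  cand1 <- find_precursor_candidates(loc, 3, window = 1)
  expect_setequal(cand1$id, "g4")   # g2 is 150 aa: excluded by the strict <
  expect_false("g2" %in% cand$id[cand$length >= 150])
  # 150 exactly is excluded everywhere
  expect_false("g2" %in% find_precursor_candidates(loc, 3, window = 3)$id)
})

test_that("validation tables count labelled loci correctly and monotonically", {
  pos <- lapply(1:4, function(k) {
    toy_ctx(c("precursor", "rre", "rsam"), seed = 210 + k)$locus
  })
  neg <- lapply(1:3, function(k) {
    toy_ctx(c("random", "transporter", "random"), seed = 220 + k)$locus
  })
  proteins <- dplyr::bind_rows(lapply(c(pos, neg), locus_proteins))
  rre_model <- toy_ctx(c("rre"), seed = 230)$models$rre
  hits <- scan_proteins(proteins, rre_model, bit_cutoff = 15)
  vt <- validate_against_labeled_loci(hits, pos, neg)
  expect_s3_class(vt, "rre_validation")
  tiers <- vt$per_tier
  expect_equal(tiers$recall[tiers$tier == "moderate"], 1)
  expect_equal(tiers$hits_in_negative_loci[tiers$tier == "moderate"], 0)
  # counts monotone non-increasing with stringency
  ord <- match(c("tolerant", "moderate", "stringent"), tiers$tier)
  expect_true(all(diff(tiers$hits_in_positive_loci[ord]) <= 0))
  expect_true(all(diff(tiers$hits_in_negative_loci[ord]) <= 0))
  expect_true(all(diff(tiers$positive_loci_detected[ord]) <= 0))

  # independent recount from the raw hit table
  hit_locus <- sub("\\|.*$", "", hits$protein_id)
  pos_ids <- vapply(pos, `[[`, character(1), "locus_id")
  for (tier in tiers$tier) {
    cut <- rre_config()$tier_bits[[tier]]
    expect_equal(tiers$hits_in_positive_loci[tiers$tier == tier],
                 sum(hits$bit_score >= cut & hit_locus %in% pos_ids))
  }

  # duplicated locus ids across labels are rejected
  expect_error(validate_against_labeled_loci(hits, pos, pos[1]),
               "both labels")
})

test_that("model overlap counts shared proteins and matches a recount", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p1", "p2", "p3", "p3", "p3"),
    model_name = c("A", "B", "A", "B", "C", "A"),
    bit_score = 30, evalue = NA_real_, env_from = 1L, env_to = 50L,
    ali_len = 50L, tiers = list("moderate"), best_fit = FALSE,
    regulator_flag = FALSE
  )
  mat <- model_overlap_matrix(hits)
  expect_equal(mat["A", "B"], 2)   # p1 and p3
  expect_equal(mat["A", "C"], 1)   # p3
  expect_equal(mat["A", "A"], 3)
  expect_equal(mat, t(mat))
  # brute-force recount oracle
  for (a in rownames(mat)) for (b in colnames(mat)) {
    pa <- unique(hits$protein_id[hits$model_name == a])
    pb <- unique(hits$protein_id[hits$model_name == b])
    expect_equal(unname(mat[a, b]), length(intersect(pa, pb)))
  }
  disjoint <- dplyr::mutate(hits,
                            model_name = rep(c("A", "B"), each = 3),
                            protein_id = sprintf("q%d", 1:6))
  m2 <- model_overlap_matrix(disjoint)
  expect_equal(unname(m2["A", "B"]), 0)
})

test_that("the model acceptance rule applies strict > and < boundaries", {
  fam <- gens_ctx$rre
  mod <- family_model(fam, n_seed = 15, name = "rre_fam")
  members <- fam$members[1:24, c("id", "description", "sequence")]
  decoys <- make_decoys(5, length_dist = 90, seed = 240)

  # 96% recall (24 members retrieved of 25 labelled positives) passes
  pos96 <- dplyr::bind_rows(members, decoys[1, ])
  rep96 <- model_acceptance_report(mod, pos96, decoys)
  expect_equal(rep96$recall, 24 / 25)
  expect_true(rep96$pass)

  # exactly 95% recall fails the strict > rule
  pos95 <- dplyr::bind_rows(members[1:19, ], decoys[1, ])
  rep95 <- model_acceptance_report(mod, pos95, decoys)
  expect_equal(rep95$recall, 0.95)
  expect_false(rep95$pass)

  # cross-class hits at exactly the bound fail the strict < rule
  cfg_fp <- rre_config(model_fp_max = 15L)
  repfp <- model_acceptance_report(mod, members, members[1:15, ], cfg_fp)
  expect_equal(repfp$cross_class_hits, 15)
  expect_false(repfp$pass)

  expect_error(model_acceptance_report(mod, members[0, ], decoys),
               "empty positive set")
})
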