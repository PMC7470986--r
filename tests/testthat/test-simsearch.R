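test_that("global alignment identity counts residue-paired columns only", {
  expect_equal(global_align("ACD", "ACD")$identity, 1.0)
  expect_equal(global_align("ACD", "AGD")$identity, 2 / 3)
  ga <- global_align("ACD", "AD")
  expect_equal(ga$alignment, c("ACD", "A-D"))
  expect_equal(ga$identity, 1.0)  # the gapped column is excluded
})

test_that("global alignment scores are symmetric and match enumeration", {
  pairs <- withr::with_seed(60, {
    replicate(6, list(
      a = paste(sample(c("A", "C", "D"), sample(2:6, 1), TRUE), collapse = ""),
      b = paste(sample(c("A", "C", "D"), sample(2:6, 1), TRUE), collapse = "")
    ), simplify = FALSE)
  })
  for (p in pairs) {
    s_ab <- global_align(p$a, p$b)$score
    s_ba <- global_align(p$b, p$a)$score
    expect_equal(s_ab, s_ba)
    expect_equal(s_ab, enum_global_score(p$a, p$b))
  }
})

test_that("local E-values follow the fixed Karlin-Altschul map", {
  seq100 <- withr::with_seed(61, paste(sample(rrescan:::AA20, 100, TRUE),
                                       collapse = ""))
  self <- local_align_evalue(seq100, seq100)
  expect_lt(self$evalue, 1e-22)        # a self-match crosses the SSN threshold

  a <- withr::with_seed(62, paste(sample(rrescan:::AA20, 50, TRUE), collapse = ""))
  b <- withr::with_seed(63, paste(sample(rrescan:::AA20, 50, TRUE), collapse = ""))
  res <- local_align_evalue(a, b, n_db = 500)
  # formula oracle applied to the reported raw score
  expect_equal(res$evalue, 0.041 * 50 * 50 * exp(-0.267 * res$raw_score) * 500,
               tolerance = 1e-12)
  # linear (hence monotone) in database size
  expect_equal(local_align_evalue(a, b, n_db = 1000)$evalue, 2 * res$evalue,
               tolerance = 1e-12)
})

test_that("greedy clustering matches an all-pairs connected-components oracle", {
  expect_equal(dplyr::n_distinct(
    greedy_cluster(tibble::tibble(id = c("a", "b"),
                                  sequence = c("ACDEFGHIKL", "ACDEFGHIKL")))$cluster), 1)
  two <- withr::with_seed(64, tibble::tibble(
    id = c("a", "b"),
    sequence = replicate(2, paste(sample(rrescan:::AA20, 60, TRUE), collapse = ""))
  ))
  expect_equal(dplyr::n_distinct(greedy_cluster(two)$cluster), 2)

  fx <- planted_cluster_fixture(seed = 101)
  cl <- greedy_cluster(fx[, c("id", "sequence")], 0.80)
  # oracle: graph over all pairs at >= 80% identity, connected components
  n <- nrow(fx)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    adj[i, j] <- adj[j, i] <-
      global_align(fx$sequence[i], fx$sequence[j])$identity >= 0.80
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  oracle <- igraph::components(g)$membership
  # identical partitions (up to label renaming)
  expect_equal(dplyr::n_distinct(cl$cluster), max(oracle))
  joined <- match(fx$id, cl$id)
  tab <- table(cl$cluster[joined], oracle)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # every member matches its representative at >= the threshold
  for (i in seq_len(nrow(cl))) {
    rep_seq <- cl$sequence[cl$id == cl$representative[i]][1]
    expect_gte(global_align(cl$sequence[i], rep_seq)$identity, 0.80)
  }
})

test_that("SSN edges are thresholded, nested, and RepNodes conflate correctly", {
  fx <- planted_cluster_fixture(seed = 102)
  ssn22 <- build_ssn(fx[, c("id", "sequence")], 22)
  ssn25 <- build_ssn(fx[, c("id", "sequence")], 25)
  expect_true(all(ssn22$edges$alignment_score >= 22))
  key <- function(e) paste(e$id_a, e$id_b)
  expect_true(all(key(ssn25$edges) %in% key(ssn22$edges)))

  # ~85% identity pairs conflate at RepNode80; conflation never adds nodes
  rn80 <- conflate_repnodes(ssn22, 0.80)
  rn60 <- conflate_repnodes(ssn22, 0.60)
  expect_lte(igraph::vcount(rn80$graph), igraph::vcount(ssn22$graph))
  expect_lte(igraph::vcount(rn60$graph), igraph::vcount(rn80$graph))
  expect_equal(igraph::vcount(rn80$graph), 3)  # one node per planted group

  # conflated edges equal recomputation from scratch on the representatives
  reps <- rn80$repnode_map
  rep_tbl <- fx[fx$id %in% unique(reps$repnode), c("id", "sequence")]
  if (nrow(rep_tbl) >= 2) {
    direct <- build_ssn(rep_tbl, 22, n_db = nrow(fx))
    expect_setequal(paste(rn80$edges$id_a, rn80$edges$id_b),
                    paste(direct$edges$id_a, direct$edges$id_b))
  }
})

test_that("identity-threshold ordering drives RepNode conflation", {
  base <- withr::with_seed(65, paste(sample(rrescan:::AA20, 100, TRUE),
                                     collapse = ""))
  p <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    sequence = c(base,
                 mutate_seq(base, 15, 66),   # ~85% identity to s1
                 mutate_seq(base, 30, 67))   # ~70% identity to s1
  )
  ssn <- build_ssn(p, 10)
  expect_equal(igraph::vcount(conflate_repnodes(ssn, 0.80)$graph), 2)
  expect_equal(igraph::vcount(conflate_repnodes(ssn, 0.60)$graph), 1)
})

test_that("diverse seed selection honours component structure and k range", {
  fx <- planted_cluster_fixture(seed = 103)
  ssn <- build_ssn(fx[, c("id", "sequence")], 22)
  comp <- igraph::components(ssn$graph)
  expect_equal(comp$no, 3)
  seeds <- select_diverse_seeds(ssn, k_range = c(5, 20), seed = 4)
  # 3 components with k_min 5: one from each plus 2 extra from the largest
  expect_length(seeds, 5)
  expect_length(unique(seeds), 5)
  picked_comp <- comp$membership[seeds]
  expect_setequal(unique(picked_comp), 1:3)
  expect_identical(seeds, select_diverse_seeds(ssn, c(5, 20), seed = 4))
  # 7 singleton components, k [5,20] -> one seed per component
  single <- withr::with_seed(68, tibble::tibble(
    id = sprintf("u%d", 1:7),
    sequence = replicate(7, paste(sample(rrescan:::AA20, 50, TRUE), collapse = ""))
  ))
  ssn1 <- build_ssn(single, 22)
  expect_length(select_diverse_seeds(ssn1, c(5, 20), seed = 1), 7)
})

test_that("center-star alignment picks the score-maximal center", {
  same <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep("MKVLAW", 3))
  aln <- msa_center_star(same)
  expect_equal(aln$rows$aligned, rep("MKVLAW", 3))

  two <- tibble::tibble(id = c("x", "y"), sequence = c("ACD", "AD"))
  expect_equal(msa_center_star(two)$rows$aligned, c("ACD", "A-D"))
  expect_error(msa_center_star(two[1, ]), "at least 2")

  # the chosen center maximises the summed pairwise score (checked
  # exhaustively for n <= 4)
  fx <- withr::with_seed(69, tibble::tibble(
    id = sprintf("q%d", 1:4),
    sequence = replicate(4, paste(sample(c("A", "C", "D", "E", "G"),
                                         sample(5:8, 1), TRUE), collapse = ""))
  ))
  sums <- vapply(seq_len(4), function(i) {
    sum(vapply(setdiff(1:4, i), function(j) {
      global_align(fx$sequence[i], fx$sequence[j])$score
    }, numeric(1)))
  }, numeric(1))
  aln <- msa_center_star(fx)
  # the center row is ungapped only up to merged-in gaps; recover it as the
  # row whose de-gapped sequence is the argmax sequence
  center_id <- fx$id[order(-sums, fx$id)[1]]
  expect_true(center_id %in% aln$rows$id)
  degap <- gsub("-", "", aln$rows$aligned[aln$rows$id == center_id])
  expect_equal(degap, fx$sequence[fx$id == center_id])
})
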