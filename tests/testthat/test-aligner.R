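# Global protein alignment, score classes, best-hit classification and
# inter-region comparison.

test_that("global alignment matches two independent oracles", {
  # reference pair: same score as Biostrings' global affine aligner
  al <- global_align("HEAGAWGHEE", "PAWHEAE")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("HEAGAWGHEE"), Biostrings::AAString("PAWHEAE"),
    substitutionMatrix = blosum62_matrix, gapOpening = 10,
    gapExtension = 0.5, type = "global")
  expect_equal(al$score, Biostrings::score(pa))

  # random pairs <= 30 aa against the dynamic-programming engine of
  # Biostrings and tiny pairs against the brute-force recursion
  set.seed(101)
  for (i in 1:20) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    al <- global_align(a, b)
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62_matrix, gapOpening = 10,
      gapExtension = 0.5, type = "global"))
    expect_equal(al$score, ref)
  }
  for (i in 1:8) {
    a <- random_protein(sample(3:9, 1))
    b <- random_protein(sample(3:9, 1))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b))
  }
})

test_that("alignment statistics behave as needle-style full-length measures", {
  set.seed(102)
  p <- random_protein(100)
  self <- global_align(p, p)
  expect_equal(self$identity, 100)
  expect_equal(self$similarity, 100)
  expect_equal(self$aligned_length, 100L)
  expect_true(self$full_length)

  for (i in 1:10) {
    a <- random_protein(sample(10:40, 1))
    b <- random_protein(sample(10:40, 1))
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(ab$identity, ba$identity)
    expect_equal(ab$similarity, ba$similarity)
    expect_lte(ab$identity, ab$similarity)
    expect_lte(ab$similarity, 100)
    expect_gte(ab$aligned_length, max(nchar(a), nchar(b)))
  }
  expect_error(global_align("", "MA"), "empty")
  expect_error(global_align("MA", "M1A"), "substitution matrix")
})

test_that("identical suffixes extend an alignment without changing similarity", {
  a <- "MKLVVNHEQW"
  b <- "MKLIVNHDQW"
  base <- global_align(a, b)
  suffix <- "AAAAAAAAAA"
  ext <- global_align(paste0(a, suffix), paste0(b, suffix))
  expect_equal(ext$similarity, base$similarity * base$aligned_length / ext$aligned_length +
                 100 * nchar(suffix) / ext$aligned_length)
  expect_equal(ext$aligned_length, base$aligned_length + nchar(suffix))
})

test_that("similarity classes follow the published score bins", {
  expect_equal(as.character(similarity_class(c(0, 10, 25, 25.1, 40, 50,
                                               60, 75, 80, 100))),
               c("none", "none", "none", "low", "low", "low",
                 "medium", "medium", "high", "high"))
})

test_that("region classification votes by best hit over all proteins", {
  set.seed(103)
  db <- simulate_phage_db(n_phages = 3L, genes_per_phage = 10L,
                          mean_len = 100L, seed = 11L)
  phage_x <- db$phage[1L]
  # 8 mildly mutated copies of phage X proteins + 1 unrelated protein
  prots <- c(vapply(db$seq[db$phage == phage_x][1:8], function(s)
    prophactr:::mutate_protein(s, 0.10), character(1)),
    random_protein(90))
  names(prots) <- sprintf("q%d", 1:9)
  cls <- classify_region(prots, db, region_label = "test")
  expect_equal(cls$top_phage, phage_x)
  expect_equal(cls$top_fraction, 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(sum(cls$family_votes), nrow(cls$best_hits))

  # permuting database record order never changes the assignment
  perm <- db[sample(nrow(db)), ]
  cls2 <- classify_region(prots, perm, region_label = "test")
  expect_equal(cls2$top_phage, cls$top_phage)
  expect_equal(cls2$top_fraction, cls$top_fraction)
  expect_equal(cls2$best_hits[order(cls2$best_hits$query_id), ],
               cls$best_hits[order(cls$best_hits$query_id), ],
               ignore_attr = TRUE)

  # exact copies: perfect assignment
  exact <- setNames(db$seq[db$phage == phage_x][1:5], sprintf("e%d", 1:5))
  cls3 <- classify_region(exact, db)
  expect_equal(cls3$top_phage, phage_x)
  expect_equal(cls3$top_fraction, 100)

  # nothing above the cutoff: unclassified
  set.seed(104)
  junk <- setNames(vapply(1:4, function(i) random_protein(60),
                          character(1)), sprintf("j%d", 1:4))
  cls4 <- classify_region(junk, db)
  expect_equal(cls4$top_phage, "unclassified")
  expect_equal(cls4$top_fraction, 0)
  expect_error(classify_region(character(0), db), "empty")
})

test_that("inter-region comparison bins scores and sees paralog asymmetry", {
  set.seed(105)
  shared <- random_protein(80)
  paralog <- prophactr:::mutate_protein(shared, 0.05)
  regA <- c(a1 = shared, a2 = paralog, a3 = random_protein(70))
  regB <- c(b1 = shared, b2 = random_protein(75))
  cmp <- compare_regions(list(A = regA, B = regB))

  # the shared identical protein scores 100 / class high in both directions
  a1b <- cmp[cmp$region_a == "A" & cmp$protein_a == "a1", ]
  expect_equal(a1b$score, 100)
  expect_equal(as.character(a1b$class), "high")
  expect_true(a1b$significant)

  # paralogy: a1 and a2 both map to b1, but B's two proteins cannot
  # both reach a high-scoring partner in A and back
  a2b <- cmp[cmp$region_a == "A" & cmp$protein_a == "a2", ]
  expect_equal(a2b$protein_b, "b1")
  n_high_AtoB <- sum(cmp$region_a == "A" & cmp$score > 75)
  n_high_BtoA <- sum(cmp$region_a == "B" & cmp$score > 75)
  expect_gt(n_high_AtoB, n_high_BtoA)

  # no shared seeds: no alignment attempted, class none
  cmp2 <- compare_regions(list(
    X = c(x1 = strrep("AC", 30)), Y = c(y1 = strrep("DE", 30))))
  expect_true(all(cmp2$score == 0))
  expect_true(all(cmp2$class == "none"))
  expect_true(all(is.na(cmp2$protein_b)))
  expect_error(compare_regions(list(A = regA)), "at least 2")
})
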