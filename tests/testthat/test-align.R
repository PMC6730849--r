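test_that("global alignment of identical sequences scores the diagonal", {
  b62 <- matloci:::subst_matrix(scoring_scheme("aa"))
  res <- align_global("ARNDC", "ARNDC")
  expect_equal(res$identity, 1)
  expect_equal(res$score, sum(diag(b62[c("A", "R", "N", "D", "C"),
                                       c("A", "R", "N", "D", "C")])))
})

test_that("aligning against an empty sequence costs one gap run", {
  res <- align_global("A", "")
  expect_equal(res$score, -(11 + 1))
})

test_that("mixed alphabets are rejected", {
  expect_error(align_global("ACGTACGTAA", "MKLWQERTYH"), "mixed alphabets")
})

test_that("global alignment equals the exhaustive-enumeration oracle", {
  set.seed(5)
  sch <- scoring_scheme("aa")
  sub <- matloci:::subst_matrix(sch)
  for (k in 1:25) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    expect_equal(align_global(a, b, sch)$score,
                 oracle_global_score(a, b, sub, 11, 1),
                 info = paste(a, b))
  }
  schn <- scoring_scheme("nt")
  subn <- matloci:::subst_matrix(schn)
  for (k in 1:25) {
    a <- random_dna(sample(1:12, 1))
    b <- random_dna(sample(1:12, 1))
    expect_equal(align_global(a, b, schn)$score,
                 oracle_global_score(a, b, subn, 5, 2),
                 info = paste(a, b))
  }
})

test_that("local nucleotide alignment matches conventions and the DP oracle", {
  expect_equal(align_local_nt("ACGT", "ACGT")$score, 8)
  expect_equal(align_local_nt("AAAA", "CCCC")$score, 0)
  set.seed(6)
  schn <- scoring_scheme("nt")
  subn <- matloci:::subst_matrix(schn)
  for (k in 1:10) {
    a <- random_dna(200)
    b <- if (k %% 2 == 0) random_dna(200) else
      paste0(random_dna(50), substr(a, 40, 160), random_dna(50))
    expect_equal(align_local_nt(a, b, schn)$score,
                 oracle_local_score(a, b, subn, 5, 2))
  }
})

test_that("compiled score engine agrees with pairwiseAlignment", {
  set.seed(8)
  sch <- scoring_scheme("aa")
  for (k in 1:10) {
    a <- random_protein(sample(5:80, 1)); b <- random_protein(sample(5:80, 1))
    s_cpp <- matloci:::align_score_matrix(
      tibble::tibble(id = "q", seq = a), tibble::tibble(id = "t", seq = b),
      sch)[1, 1]
    s_bio <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = matloci:::subst_matrix(sch),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(s_cpp, s_bio)
  }
})

test_that("score is symmetric and monotone under shared suffixes", {
  set.seed(9)
  sch <- scoring_scheme("aa")
  for (k in 1:8) {
    a <- random_protein(sample(3:20, 1)); b <- random_protein(sample(3:20, 1))
    expect_equal(align_global(a, b, sch)$score, align_global(b, a, sch)$score)
    sfx <- random_protein(6)
    expect_gte(align_global(paste0(a, sfx), paste0(b, sfx), sch)$score,
               align_global(a, b, sch)$score)
  }
})

test_that("reciprocal-best-hit role assignment handles the decision cases", {
  set.seed(10)
  sxi2 <- random_protein(150)
  ste3 <- random_protein(200)
  panel <- seq_set(id = c("p1", "p2"), seq = c(sxi2, ste3), alphabet = "aa")
  panel$role <- c("SXI2", "STE3")

  # exact copy present: unique reciprocal assignment
  prot <- seq_set(id = c("gA", "gB", "gC"),
                  seq = c(sxi2, ste3, random_protein(180)), alphabet = "aa")
  roles <- assign_roles(prot, panel)
  expect_equal(roles$gene_id[roles$role == "SXI2"], "gA")
  expect_equal(roles$gene_id[roles$role == "STE3"], "gB")
  expect_true(all(roles$flag[roles$assigned] == "unique"))

  # one-way best: the best query for one role prefers another role
  prot2 <- seq_set(id = c("g1"), seq = sxi2, alphabet = "aa")
  roles2 <- assign_roles(prot2, panel)
  r_ste3 <- roles2[roles2$role == "STE3", ]
  expect_equal(r_ste3$flag, "one_way")
  expect_true(is.na(r_ste3$gene_id))

  # tie: two identical queries; lexicographically smaller id wins
  prot3 <- seq_set(id = c("gB", "gA"), seq = c(sxi2, sxi2), alphabet = "aa")
  roles3 <- assign_roles(prot3, panel[panel$role == "SXI2", ])
  expect_equal(roles3$flag, "tie")
  expect_equal(roles3$gene_id, "gA")
})

test_that("scores below the floor stay unassigned", {
  set.seed(12)
  panel <- seq_set(id = "p1", seq = random_protein(200), alphabet = "aa")
  panel$role <- "STE3"
  prot <- seq_set(id = "g1", seq = random_protein(30), alphabet = "aa")
  roles <- assign_roles(prot, panel)
  expect_false(roles$assigned)
})

test_that("STE3 typing calls the closer class and flags ties unresolved", {
  set.seed(13)
  a_ref <- random_protein(220)
  alpha_ref <- random_protein(220)
  refs <- seq_set(id = c("ra", "rb"), seq = c(a_ref, alpha_ref),
                  alphabet = "aa")
  refs$class <- c("a", "alpha")
  expect_equal(type_ste3(alpha_ref, refs)$type, "alpha")
  expect_equal(type_ste3(a_ref, refs)$type, "a")

  # identical references: exactly equidistant -> unresolved
  refs2 <- refs; refs2$seq <- c(a_ref, a_ref)
  expect_equal(type_ste3(a_ref, refs2)$type, "unresolved")
  expect_error(type_ste3(a_ref, refs[refs$class == "a", ]), "alpha")
})
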