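test_that("NG86 counts match the genetic code on canonical pairs", {
  # third-position GAA->GAG is synonymous (Glu)
  r <- ng86_counts("GAA", "GAG")
  expect_equal(r$Sd, 1); expect_equal(r$Nd, 0)

  # TTT: only T->C at position 3 is synonymous among the 9 one-step changes
  r2 <- ng86_counts("TTT", "TTT")
  expect_equal(r2$s_a, 1 / 3)
  expect_equal(r2$Sd, 0); expect_equal(r2$Nd, 0)

  # two-step pair averaged over orderings: K->R->R and K->K->R
  r3 <- ng86_counts("AAA", "AGG")
  expect_equal(r3$Sd, 1); expect_equal(r3$Nd, 1)

  expect_error(ng86_counts("TAA", "GAA"), "sense codon")
})

test_that("NG86 equals the path-enumeration oracle on random codon pairs", {
  sense <- matloci:::codon_info()$sense
  set.seed(41)
  pairs <- cbind(sample(sense, 60, TRUE), sample(sense, 60, TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- ng86_counts(pairs[i, 1], pairs[i, 2])
    want <- oracle_ng86(pairs[i, 1], pairs[i, 2])
    expect_equal(got$s_a, want$s_a, info = paste(pairs[i, ], collapse = "-"))
    expect_equal(got$Sd, want$Sd, info = paste(pairs[i, ], collapse = "-"))
    expect_equal(got$Nd, want$Nd, info = paste(pairs[i, ], collapse = "-"))
  }
})

test_that("codon alignment drops gapped pairs and rejects broken frames", {
  set.seed(42)
  cds <- matloci:::random_cds(300, 0.5)
  aln <- codon_align(cds, cds)
  expect_equal(aln$n_codons, 99L)  # terminal stop trimmed
  expect_equal(aln$n_dropped_gap, 0L)

  # single in-frame 3-nt insertion: exactly one dropped pair
  ins_at <- 150
  cds_ins <- paste0(substr(cds, 1, ins_at), "GCT",
                    substr(cds, ins_at + 1, nchar(cds)))
  aln2 <- codon_align(cds, cds_ins)
  expect_equal(aln2$n_dropped_gap, 1L)
  expect_equal(aln2$n_codons, 99L)

  expect_error(codon_align(substr(cds, 1, 100), cds), "divisible by 3")
  bad <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, nchar(cds)))
  expect_error(codon_align(bad, cds, name_a = "mutant"), "mutant")
})

test_that("dS estimation handles identity, symmetry, and saturation", {
  set.seed(43)
  cds <- matloci:::random_cds(600, 0.5)
  est <- estimate_ds(codon_align(cds, cds), bootstrap_B = 50, seed = 1)
  expect_equal(est$dS, 0)
  expect_equal(est$dN, 0)
  expect_equal(est$status, "ok")
  expect_equal(est$S_sites + est$N_sites, 3 * est$n_codons)

  # role swap leaves the estimate unchanged
  cds2 <- matloci:::random_cds(600, 0.5)
  e12 <- estimate_ds(codon_align(cds, cds2), bootstrap_B = 0)
  e21 <- estimate_ds(codon_align(cds2, cds), bootstrap_B = 0)
  expect_equal(e12$dS, e21$dS)
  expect_equal(e12$dN, e21$dN)

  expect_error(estimate_ds(codon_align("ATGAAATGA", "ATGAAATGA")), "floor")
})

test_that("saturated synonymous divergence is reported as undefined", {
  # construct an alignment where every synonymous site differs:
  # TTT vs TTC is a synonymous third-position difference; with pS > 3/4 the
  # JC logarithm argument goes non-positive
  pairs <- tibble::tibble(codon_a = rep("TTT", 50), codon_b = rep("TTC", 50))
  aln <- structure(list(pairs = pairs, n_codons = 50L, n_dropped_gap = 0L),
                   class = "codon_alignment")
  est <- estimate_ds(aln, bootstrap_B = 0)
  expect_equal(est$status, "undefined")
  expect_true(is.na(est$dS))
  expect_gt(est$pS, 0.75)
})

test_that("JC correction is monotone and exceeds the raw proportion", {
  jc <- function(p) -(3 / 4) * log(1 - (4 / 3) * p)
  ps <- seq(0.01, 0.70, by = 0.01)
  expect_true(all(diff(jc(ps)) > 0))
  expect_true(all(jc(ps) >= ps))
})

test_that("closest-pair calls label pairs by allele class", {
  set.seed(44)
  base <- matloci:::random_cds(900, 0.5)
  mutate_cds <- function(x, n) {
    ch <- strsplit(x, "")[[1]]
    idx <- sample(4:(length(ch) - 3), n)
    ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  tbl <- tibble::tibble(
    gene = "g1",
    strain = c("s1", "s2", "s3"),
    cds = c(mutate_cds(base, 40), mutate_cds(base, 5), base))
  calls <- closest_pair_calls(tbl, c(s1 = "A1", s2 = "A2", s3 = "A2"))
  expect_equal(calls$status, "called")
  expect_equal(calls$most_similar_pair, "s2|s3")
  expect_equal(calls$pair_classes, "A2/A2")

  # identical alleles tie -> ambiguous
  tbl2 <- tbl; tbl2$cds <- rep(base, 3)
  expect_equal(closest_pair_calls(tbl2, c(s1 = "A1", s2 = "A2", s3 = "A2"))$status,
               "ambiguous")

  # missing allele -> not assessed
  tbl3 <- tbl[1:2, ]
  expect_equal(closest_pair_calls(tbl3, c(s1 = "A1", s2 = "A2"))$status,
               "not_assessed")
})

test_that("the pooled t-test matches closed forms and stats::t.test", {
  r <- compare_ds_sets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.5)

  r2 <- compare_ds_sets(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r2$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r2$p_value, 1 - stats::pt(-1.224745, 4), tolerance = 1e-6)

  set.seed(45)
  x <- rnorm(12, 0.03, 0.01); y <- rnorm(15, 0.01, 0.01)
  r3 <- compare_ds_sets(x, y)
  ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "greater")
  expect_equal(r3$statistic, unname(ht$statistic))
  expect_equal(r3$p_value, ht$p.value)
  expect_equal(r3$df, unname(ht$parameter))

  expect_error(compare_ds_sets(c(1), c(1, 2)), "at least 2")

  td <- generics::tidy(r3)
  expect_equal(td$statistic, r3$statistic)
  expect_equal(td$p.value, r3$p_value)
})

test_that("degenerate zero-variance sets resolve deterministically", {
  expect_equal(compare_ds_sets(c(1, 1), c(1, 1))$p_value, 0.5)
  r <- compare_ds_sets(c(2, 2), c(1, 1))
  expect_equal(r$p_value, 0)
  expect_true(is.infinite(r$statistic))
})

test_that("breakpoint windows score lower than inversion interiors when planted", {
  res <- validate_breakpoint_divergence(n_reps = 3, seed = 81, homogenize = TRUE)
  expect_true(all(!is.na(res$p_value)))
  expect_gte(mean(res$p_value < 0.05), 2 / 3)  # majority of replicates
})

test_that("insufficient windows in a class raise an informative error", {
  track <- window_similarity(random_dna(4000), random_dna(4000),
                             fragment = 1000)
  blocks <- detect_blocks(mk_anchor_tbl(rev(1:4) * 500, rep("flipped", 4)))
  expect_error(breakpoint_divergence_test(track, blocks), "insufficient")
})
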