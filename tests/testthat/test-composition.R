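test_that("GC windows tile the sequence and hit exact extremes", {
  tr <- gc_windows(strrep("G", 2000), window = 2000)
  expect_equal(tr$value, 100)
  tr2 <- gc_windows(strrep("AT", 1000), window = 2000)
  expect_equal(tr2$value, 0)
  expect_equal(nrow(gc_windows("", window = 2000)), 0L)
})

test_that("coverage-weighted window means reproduce whole-sequence GC exactly", {
  set.seed(51)
  for (k in 1:5) {
    s <- random_dna(sample(3000:9000, 1), gc = runif(1, 0.3, 0.7))
    tr <- gc_windows(s, window = 2000)
    w <- tr$end - tr$start
    expect_equal(sum(tr$value * w) / sum(w), gc_percent(s), tolerance = 1e-12)
  }
})

test_that("ambiguity codes drop out of numerator and denominator", {
  tr <- gc_windows("GGNNAA", window = 6)
  expect_equal(tr$value, 100 * 2 / 4)
})

test_that("per-CDS GC is strand-invariant and carries a genome mean", {
  sim <- cached_pair_sim()
  st <- names(sim$annotations)[1]
  ann <- mat_region_annotation(sim, st)
  tab <- cds_gc(ann, sim$assemblies[[st]])
  expect_equal(nrow(tab), nrow(ann))
  expect_true(is.numeric(attr(tab, "genome_gc")))

  flipped <- ann
  flipped$strand <- chartr("+-", "-+", flipped$strand)
  tab2 <- cds_gc(flipped, sim$assemblies[[st]])
  expect_equal(tab$gc, tab2$gc)
})

test_that("RSCU obeys its defining identities", {
  # uniform usage in a two-codon family
  tab <- rscu(c("ATGGAAGAGTAA"))
  fam_e <- tab[tab$aa == "E", ]
  expect_equal(fam_e$rscu, c(1, 1))
  # single-codon family (Met) has RSCU 1 by convention
  expect_equal(tab$rscu[tab$aa == "M"], 1)

  # two-codon family with only one codon used -> 2 and 0
  tab2 <- rscu("ATGGAAGAATAA")
  expect_equal(sort(tab2$rscu[tab2$aa == "E"]), c(0, 2))

  # family means equal 1 whenever observed
  set.seed(52)
  tab3 <- rscu(replicate(5, matloci:::random_cds(300, 0.6)))
  means <- tapply(tab3$rscu, tab3$aa, mean)
  expect_true(all(abs(means - 1) < 1e-12))

  expect_error(rscu("ATGTAAGAATAA"), "internal stop")
})

test_that("AT-biased MAT genes use GC-ending codons less", {
  sim <- cached_trio_sim()
  st <- names(sim$annotations)[1]
  ann <- sim$annotations[[st]]
  asm <- sim$assemblies[[st]]
  mat_genes <- ann[ann$contig == sim$truth$mat_contig &
                     !(ann$role %in% c("MF")), ]
  bg_genes <- ann[ann$contig != sim$truth$mat_contig, ]
  cds_of <- function(g) vapply(seq_len(nrow(g)), function(i)
    gene_cds(g[i, ], asm), character(1))
  r_mat <- rscu(cds_of(mat_genes))
  r_bg <- rscu(cds_of(bg_genes))
  gc_end <- function(tab) {
    sel <- grepl("[GC]$", tab$codon) & tab$family_size > 1
    mean(tab$rscu[sel])
  }
  expect_lt(gc_end(r_mat), gc_end(r_bg))
})

test_that("exact rank-sum p-values come from the permutation null", {
  r <- rank_sum_test(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 6)
  expect_equal(r$method, "exact")

  # x == y: both one-sided p-values at least 1/2
  x <- c(1, 2, 3, 4)
  expect_gte(rank_sum_test(x, x, alternative = "less")$p_value, 0.5)
  expect_gte(rank_sum_test(x, x, alternative = "greater")$p_value, 0.5)

  # degenerate: all values identical
  rd <- rank_sum_test(rep(2, 3), rep(2, 5))
  expect_true(rd$degenerate)
  expect_equal(rd$p_value, 1)
})

test_that("exact rank-sum agrees with wilcox.test when there are no ties", {
  set.seed(53)
  for (k in 1:10) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    r <- rank_sum_test(x, y, alternative = "less")
    w <- stats::wilcox.test(x, y, alternative = "less", exact = TRUE)
    expect_equal(r$p_value, w$p.value, tolerance = 1e-12)
    expect_equal(r$U, unname(w$statistic))
  }
})

test_that("exact rank-sum handles ties via midranks", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  r <- rank_sum_test(x, y, alternative = "less")
  expect_equal(r$method, "exact")
  # independent check by direct enumeration of all 8-choose-4 subsets
  comb <- c(x, y); rk <- rank(comb)
  W <- sum(rk[1:4])
  subsets <- utils::combn(8, 4)
  ws <- apply(subsets, 2, function(ix) sum(rk[ix]))
  expect_equal(r$p_value, mean(ws <= W))
})

test_that("normal approximation tracks the exact method", {
  set.seed(54)
  x <- rnorm(20); y <- rnorm(20)
  comb <- c(x, y); rk <- rank(comb)
  U <- sum(rk[1:20]) - 20 * 21 / 2
  p_exact <- matloci:::ranksum_exact_p(rk, 20, sum(rk[1:20]), "less")
  p_norm <- matloci:::ranksum_normal_p(rk, 20, 20, U, "less")
  expect_lt(abs(p_exact - p_norm), 0.01)
})

test_that("planted GC depression is detected by the rank-sum contrast", {
  res <- validate_composition_recovery(n_reps = 4, seed = 61)
  expect_true(all(res$detected))
  expect_true(all(res$mat_gc < res$background_gc))
})
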