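test_that("identical regions anchor every gene colinearly", {
  sim <- cached_pair_sim()
  st <- names(sim$annotations)[1]
  ga <- mat_region_annotation(sim, st)
  pa <- strain_proteome(ga, sim$assemblies[[st]])
  anchors <- anchor_map(ga, pa, ga, pa)
  expect_equal(nrow(anchors), nrow(ga))
  expect_true(all(anchors$rel_orientation == "same"))
  expect_true(all(diff(anchors$pos_b) > 0))
  blocks <- detect_blocks(anchors)
  expect_equal(nrow(blocks$blocks), 1L)
  expect_equal(blocks$blocks$orientation, "colinear")
  expect_equal(nrow(blocks$breakpoints), 0L)
})

test_that("a tandem duplicate anchors only its reciprocally best copy", {
  sim <- cached_pair_sim()
  st <- names(sim$annotations)[1]
  ga <- mat_region_annotation(sim, st)
  pa <- strain_proteome(ga, sim$assemblies[[st]])
  # duplicate one gene in region B at a shifted position
  gb <- ga
  dup <- ga[5, ]
  dup$gene_id <- "dup.copy"
  dup$start <- max(ga$end) + 500L
  dup$end <- dup$start + (ga$end[5] - ga$start[5])
  gb <- dplyr::bind_rows(gb, dup)
  pb <- pa
  pb <- dplyr::bind_rows(pb, tibble::tibble(id = "dup.copy", seq = pa$seq[5],
                                            desc = ""))
  anchors <- anchor_map(ga, pa, gb, pb)
  expect_equal(sum(anchors$gene_b %in% c(ga$gene_id[5], "dup.copy")), 1L)
})

test_that("empty regions give empty anchor lists", {
  sim <- cached_pair_sim()
  st <- names(sim$annotations)[1]
  ga <- mat_region_annotation(sim, st)
  pa <- strain_proteome(ga, sim$assemblies[[st]])
  empty_ann <- ga[0, ]
  empty_prot <- pa[0, ]
  expect_equal(nrow(anchor_map(ga, pa, empty_ann, empty_prot)), 0L)
})

test_that("fully reversed anchors form a single inverted block", {
  anc <- mk_anchor_tbl(rev(seq_len(8)) * 1000, rep("flipped", 8))
  blocks <- detect_blocks(anc)
  expect_equal(nrow(blocks$blocks), 1L)
  expect_equal(blocks$blocks$orientation, "inverted")
  expect_equal(nrow(blocks$breakpoints), 0L)
})

test_that("short runs become singletons rather than blocks", {
  # one flipped anchor inside a colinear run cannot seed a two-anchor block
  pos_b <- c(1000, 2000, 1500, 3000, 4000, 5000)
  ori <- c("same", "same", "flipped", "same", "same", "same")
  anc <- mk_anchor_tbl(pos_b, ori)
  blocks <- detect_blocks(anc, min_anchors = 2)
  expect_equal(nrow(blocks$singletons), 1L)
  expect_equal(blocks$singletons$gene_a, "a03")
  expect_equal(nrow(blocks$blocks), 2L)
  expect_true(all(blocks$blocks$orientation == "colinear"))
})

test_that("greedy blocks equal the exhaustive minimum monotone partition", {
  set.seed(21)
  for (k in 1:40) {
    n <- sample(4:10, 1)
    ori <- sample(c("same", "flipped"), n, replace = TRUE)
    pos_b <- sample(seq_len(n) * 1000)
    anc <- mk_anchor_tbl(pos_b, ori)
    blocks <- detect_blocks(anc, min_anchors = 1)
    greedy_runs <- nrow(blocks$blocks)
    expect_equal(greedy_runs, oracle_min_partition(anc),
                 info = paste("case", k))
  }
})

test_that("simulated A1/A2 pairs show exactly the two planted inversions", {
  sim <- cached_pair_sim()
  sts <- names(sim$annotations)
  ga <- mat_region_annotation(sim, sts[1])
  gb <- mat_region_annotation(sim, sts[2])
  anchors <- anchor_map(ga, strain_proteome(ga, sim$assemblies[[sts[1]]]),
                        gb, strain_proteome(gb, sim$assemblies[[sts[2]]]))
  blocks <- detect_blocks(anchors)
  inv <- blocks$blocks[blocks$blocks$orientation == "inverted", ]
  expect_equal(nrow(inv), 2L)
  # each inverted block lies within one intergenic interval of its segment
  segs <- sim$truth$inversion_segments
  for (i in seq_len(2)) {
    expect_gte(inv$a_start[i], segs[[i]]$lo - 2000)
    expect_lte(inv$a_end[i], segs[[i]]$hi + 2000)
  }
})

test_that("window similarity of identical regions saturates at 2 * fragment", {
  set.seed(23)
  s <- random_dna(10000, gc = 0.55)
  track <- window_similarity(s, s, fragment = 1000)
  expect_equal(nrow(track), 10L)
  expect_true(all(!track$partial))
  expect_true(all(track$value == 2000))
})

test_that("window similarity is strand-symmetric and flags partial windows", {
  set.seed(24)
  q <- random_dna(5500)
  t1 <- random_dna(6000)
  tr1 <- window_similarity(q, t1, fragment = 1000)
  tr2 <- window_similarity(q, revcomp(t1), fragment = 1000)
  expect_equal(tr1$value, tr2$value)
  expect_equal(sum(!tr1$partial), 5L)  # floor(5500/1000)
  expect_equal(sum(tr1$partial), 1L)
  expect_error(window_similarity(q, t1, fragment = 50), "degenerate")
})

test_that("a replaced segment produces a local similarity dip", {
  set.seed(25)
  q <- random_dna(8000)
  t <- q
  substr(q, 3001, 4000) <- random_dna(1000)
  track <- window_similarity(q, t, fragment = 1000)
  expect_lt(track$value[4], min(track$value[-4]))
})
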