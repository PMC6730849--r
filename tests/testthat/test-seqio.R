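test_that("FASTA parsing normalizes, preserves order, and round-trips", {
  s <- parse_fasta(">s1\nacgt")
  expect_equal(nrow(s), 1L)
  expect_equal(s$id, "s1")
  expect_equal(s$seq, "ACGT")

  expect_equal(nrow(parse_fasta("")), 0L)

  set.seed(11)
  ss <- seq_set(id = c("a", "b", "c"),
                seq = c(random_dna(75), random_dna(130), random_dna(10)),
                desc = c("first record", "", "third"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ss, path)
  back <- read_fasta(path)
  expect_equal(back$id, ss$id)
  expect_equal(back$seq, ss$seq)
  expect_equal(back$desc, ss$desc)
})

test_that("FASTA validation rejects duplicate ids and bad characters", {
  expect_error(parse_fasta(">a\nACGT\n>a\nGGGG"), "duplicate")
  expect_error(seq_set(id = "x", seq = "AC!T"), "position 3")
})

test_that("GFF3 coordinates convert to half-open 0-based and back", {
  txt <- c("##gff-version 3",
           "ctg1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
           "ctg1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1;Parent=g1",
           "ctg1\tsrc\tCDS\t101\t198\t.\t+\t0\tID=c1;Parent=m1")
  ann <- parse_gff3(txt)
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 200L)
  expect_equal(ann$cds_starts[[1]], 100L)
  expect_equal(ann$cds_ends[[1]], 198L)
  # 98 nt of CDS: flagged coding-incomplete, not rejected
  expect_false(ann$coding_complete[1])

  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  again <- read_gff3(path)
  expect_equal(again$start, ann$start)
  expect_equal(again$end, ann$end)
  expect_equal(again$cds_starts, ann$cds_starts)
})

test_that("feature lines after ##FASTA are treated as sequence payload", {
  txt <- c("##gff-version 3",
           "ctg1\tsrc\tgene\t11\t40\t.\t+\t.\tID=g1",
           "ctg1\tsrc\tmRNA\t11\t40\t.\t+\t.\tID=m1;Parent=g1",
           "ctg1\tsrc\tCDS\t11\t40\t.\t+\t0\tID=c1;Parent=m1",
           "##FASTA", ">ctg1", strrep("ACGT", 20))
  ann <- parse_gff3(txt)
  expect_equal(nrow(ann), 1L)
  expect_true(ann$coding_complete[1])
})

test_that("malformed GFF3 coordinates are rejected with a line number", {
  txt <- c("##gff-version 3", "ctg1\tsrc\tgene\t200\t101\t.\t+\t.\tID=g1")
  expect_error(parse_gff3(txt), "line 2")
})

test_that("CDS on a contig absent from the assembly is an error", {
  asm <- seq_set(id = "other", seq = "ACGT")
  txt <- c("##gff-version 3",
           "ctg1\tsrc\tgene\t1\t6\t.\t+\t.\tID=g1",
           "ctg1\tsrc\tmRNA\t1\t6\t.\t+\t.\tID=m1;Parent=g1",
           "ctg1\tsrc\tCDS\t1\t6\t.\t+\t0\tID=c1;Parent=m1")
  expect_error(parse_gff3(txt, assembly = asm), "unknown contig")
})

test_that("BED intervals satisfy start = GFF3 start - 1, end = GFF3 end", {
  ann <- parse_gff3(c("##gff-version 3",
                      "ctg1\tsrc\tgene\t101\t200\t.\t-\t.\tID=g1"))
  bed <- as_bed(ann)
  expect_equal(bed$start, 100L)  # = GFF3 start - 1
  expect_equal(bed$end, 200L)    # = GFF3 end
  expect_equal(bed$strand, "-")
})

test_that("Newick writing round-trips topology and branch lengths", {
  expect_equal(write_newick(read_newick("(A:1,B:2);")), "(A:1,B:2);")
  nwk <- "((t1:0.12345678901,t2:0.2):0.05,t3:1.7,t4:0.3);"
  tr <- read_newick(nwk)
  back <- read_newick(write_newick(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(back)
  expect_equal(d1[rownames(d2), colnames(d2)], d2, tolerance = 1e-9)
  # trifurcating root survives the round-trip
  expect_equal(back$Nnode, tr$Nnode)
})

test_that("unlabeled tips are rejected", {
  tr <- read_newick("(A:1,B:2);")
  tr$tip.label[2] <- ""
  expect_error(write_newick(tr), "labelled")
})

test_that("strand-aware CDS extraction reverse-complements minus genes", {
  asm <- seq_set(id = "c", seq = "AAATGCATCCC")
  ann <- new_ann <- parse_gff3(c("##gff-version 3",
                                 "c\tsrc\tgene\t3\t8\t.\t-\t.\tID=g1",
                                 "c\tsrc\tmRNA\t3\t8\t.\t-\t.\tID=m1;Parent=g1",
                                 "c\tsrc\tCDS\t3\t8\t.\t-\t0\tID=x;Parent=m1"))
  expect_equal(gene_cds(ann[1, ], asm), revcomp("ATGCAT"))
})
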