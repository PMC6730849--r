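test_that("the full pipeline recovers the planted allele classes", {
  sim <- cached_trio_sim()
  report <- run_characterize(sim, seed = 5)
  truth <- setNames(sim$truth$strains$class, sim$truth$strains$strain_id)
  got <- setNames(report$reports$allele, report$reports$genome_id)
  expect_equal(got[names(truth)], truth)
  expect_true(all(report$reports$linked))
  expect_equal(unique(report$reports$distance_bp), sim$truth$pr_hd_gap)

  # synteny between the A1 and an A2 strain shows the two inversions
  expect_equal(sum(report$synteny$blocks$blocks$orientation == "inverted"), 2L)

  # composition contrast detects the AT shift in every strain
  expect_true(all(report$composition$summary$mat_gc <
                    report$composition$summary$background_gc))
  expect_true(all(report$composition$summary$p_value < 0.05))

  # trio divergence ran and found the suppression signal
  expect_false(is.null(report$divergence$ttest))
  expect_lt(report$divergence$ttest$p_value, 0.05)

  # genealogy screen ran over STE3 and the background controls; with a
  # single A1 tip the class split is trivial, so no mating-type call here
  g <- report$genealogy
  expect_true("STE3" %in% g$role)
  expect_true(all(g$pattern %in% c("mating_type", "species", "mixed")))

  gl <- generics::glance(report)
  expect_equal(gl$n_strains, 3L)
  expect_equal(gl$n_inverted_blocks, 2L)
})

test_that("the pipeline is deterministic for a fixed config and seed", {
  sim <- cached_pair_sim()
  r1 <- run_characterize(sim, seed = 9)
  sim_cache$pair_report <- r1
  r2 <- run_characterize(sim, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report_bundle(r1, d1)
  write_report_bundle(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("a missing reference panel is an error", {
  sim <- cached_pair_sim()
  stripped <- sim; stripped$truth <- NULL
  expect_error(run_characterize(stripped), "reference panel required")
})

test_that("report bundles carry the expected artifacts", {
  rep <- sim_cache$pair_report %||% run_characterize(cached_pair_sim(), seed = 9)
  dir <- withr::local_tempdir()
  write_report_bundle(rep, dir)
  expect_true(file.exists(file.path(dir, "mat_reports.tsv")))
  expect_true(file.exists(file.path(dir, "blocks.tsv")))
  expect_true(file.exists(file.path(dir, "core_mat.bed")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  bed <- read.table(file.path(dir, "core_mat.bed"), sep = "\t")
  expect_true(all(bed$V3 > bed$V2))
})

test_that("flat key=value configs parse with sections and types", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "[simulate]", "n_species = 2", "seed=7",
               "homogenize_interior = TRUE", "[windows]", "window = 2000"),
             path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$simulate$n_species, 2)
  expect_equal(cfg$simulate$seed, 7)
  expect_true(cfg$simulate$homogenize_interior)
  expect_equal(cfg$windows$window, 2000)
  writeLines("oops", path)
  expect_error(read_pipeline_config(path), "key=value")
})

test_that("autoplot and tidy methods return the expected object types", {
  sim <- cached_pair_sim()
  st <- names(sim$assemblies)[1]
  track <- gc_windows(sim$assemblies[[st]]$seq[1])
  expect_s3_class(ggplot2::autoplot(track), "ggplot")

  ga <- mat_region_annotation(sim, names(sim$annotations)[1])
  gb <- mat_region_annotation(sim, names(sim$annotations)[2])
  anchors <- anchor_map(ga, strain_proteome(ga, sim$assemblies[[1]]),
                        gb, strain_proteome(gb, sim$assemblies[[2]]))
  blocks <- detect_blocks(anchors)
  expect_s3_class(ggplot2::autoplot(blocks), "ggplot")
  td <- generics::tidy(blocks)
  expect_s3_class(td, "tbl_df")
  gl <- generics::glance(blocks)
  expect_equal(gl$n_inverted, 2L)
})
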