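#' Collect allele sequences across simulated strains by template gene name
#'
#' Simulated gene ids are `<strain>.<name>`, so orthologs can be gathered
#' exactly from the truth record; this is the fast path for replicate
#' parameter-recovery studies (the inference-based path is
#' [collect_alleles()]).
#'
#' @param sim A `mat_sim`.
#' @param genes Template gene names (e.g. `"STE3"`, `"fil03"`).
#' @return A tibble: `gene`, `strain`, `gene_id`, `role`, `cds`.
#' @export
collect_alleles_by_name <- function(sim, genes) {
  rows <- list()
  for (st in names(sim$annotations)) {
    ann <- sim$annotations[[st]]
    ids <- sprintf("%s.%s", st, genes)
    hit <- match(ids, ann$gene_id)
    for (k in seq_along(genes)) {
      if (is.na(hit[k])) next
      rows[[length(rows) + 1L]] <- tibble(
        gene = genes[k], strain = st, gene_id = ids[k],
        role = ann$role[hit[k]],
        cds = gene_cds(ann[hit[k], ], sim$assemblies[[st]]))
    }
  }
  bind_rows(rows)
}

core_companion_names <- function(sim) {
  layout <- sim$truth$layout
  setdiff(layout$name, c("MF", "STE3", "SXI"))
}

#' Inversion-recovery study over simulated A1/A2 pairs
#'
#' Each replicate simulates an A1/A2 strain pair with the default planted
#' inversions, maps ortholog anchors between the two MAT contigs by
#' reciprocal best hit, detects synteny blocks, and records whether exactly
#' two inverted blocks are found with every detected breakpoint interval
#' overlapping a planted one.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @return A tibble with one row per replicate: `n_inverted`,
#'   `breakpoints_ok`, `recovered`.
#' @export
validate_inversion_recovery <- function(n_reps = 100L, seed = 1L) {
  rows <- map(seq_len(n_reps), function(k) {
    cfg <- sim_config(n_species = 1L, strains_per_species = c("A1", "A2"),
                      n_background_contigs = 0L,
                      seed = child_seed(seed, k))
    sim <- simulate_dataset(cfg)
    sts <- names(sim$annotations)
    mat_genes <- function(st) {
      ann <- sim$annotations[[st]]
      ann[ann$contig == sim$truth$mat_contig, ]
    }
    ga <- mat_genes(sts[1L]); gb <- mat_genes(sts[2L])
    anchors <- anchor_map(ga, strain_proteome(ga, sim$assemblies[[sts[1L]]]),
                          gb, strain_proteome(gb, sim$assemblies[[sts[2L]]]))
    blocks <- detect_blocks(anchors)
    n_inv <- sum(blocks$blocks$orientation == "inverted")
    planted <- unlist(map(sim$truth$breakpoint_intervals,
                          function(b) list(b$left, b$right)), recursive = FALSE)
    bp_ok <- nrow(blocks$breakpoints) > 0L &&
      all(map_lgl(seq_len(nrow(blocks$breakpoints)), function(i) {
        lo <- blocks$breakpoints$a_lo[i]; hi <- blocks$breakpoints$a_hi[i]
        any(map_lgl(planted, ~ .x[2L] > lo && .x[1L] < hi))
      }))
    tibble(n_inverted = n_inv, breakpoints_ok = bp_ok,
           recovered = n_inv == 2L && bp_ok)
  })
  bind_rows(rows)
}

#' Recombination-suppression recovery study (three-strain trios)
#'
#' Each replicate simulates a one-species trio (one A1 strain, two A2
#' strains), estimates per-gene dS for the between-mating-type comparison
#' (A1 vs the shared A2) and the within-mating-type comparison (A2 vs the
#' shared A2) over the core companion genes, runs the one-sided t-test, and
#' computes the fraction of core genes whose closest pair is A2/A2.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param suppression If `FALSE`, `mat_suppression_extra` is set to zero
#'   (null scenario).
#' @return A tibble per replicate: `p_value`, `t_stat`, `frac_a2a2`,
#'   `n_genes`.
#' @export
validate_suppression_recovery <- function(n_reps = 50L, seed = 1L,
                                          suppression = TRUE) {
  rows <- map(seq_len(n_reps), function(k) {
    cfg <- sim_config(n_species = 1L,
                      strains_per_species = c("A1", "A2", "A2"),
                      mat_suppression_extra = if (suppression) 0.02 else 0,
                      n_background_contigs = 0L,
                      seed = child_seed(seed, 1000L + k))
    sim <- simulate_dataset(cfg)
    res <- trio_ds_truth(sim, seed = child_seed(seed, 2000L + k))
    tibble(p_value = res$ttest$p_value, t_stat = res$ttest$statistic,
           frac_a2a2 = res$frac_a2a2, n_genes = res$n_genes)
  })
  bind_rows(rows)
}

# dS trio analysis using truth-based allele collection (fast path).
trio_ds_truth <- function(sim, seed = 1L) {
  strains <- sim$truth$strains
  a1 <- strains$strain_id[strains$class == "A1"][1L]
  a2 <- strains$strain_id[strains$class == "A2"]
  ref <- a2[2L]; other <- a2[1L]
  genes <- core_companion_names(sim)
  alleles <- collect_alleles_by_name(sim, genes)
  between <- numeric(0); within <- numeric(0); call_ok <- logical(0)
  for (g in genes) {
    sub <- alleles[alleles$gene == g, ]
    cds <- setNames(sub$cds, sub$strain)
    if (!all(c(a1, ref, other) %in% names(cds))) next
    ds_pair <- function(x, y) {
      tryCatch(estimate_ds(codon_align(cds[[x]], cds[[y]]), bootstrap_B = 0L,
                           seed = seed)$dS,
               error = function(e) NA_real_)
    }
    db <- ds_pair(a1, ref); dw <- ds_pair(other, ref)
    if (!is.na(db) && !is.na(dw)) {
      between <- c(between, db); within <- c(within, dw)
    }
    sc <- c(a1a2 = local_score(cds[[a1]], cds[[ref]]),
            a1a2b = local_score(cds[[a1]], cds[[other]]),
            a2a2 = local_score(cds[[other]], cds[[ref]]))
    call_ok <- c(call_ok, sc["a2a2"] > max(sc[c("a1a2", "a1a2b")]))
  }
  list(ttest = compare_ds_sets(between, within),
       frac_a2a2 = mean(call_ok), n_genes = length(between))
}

#' Trans-species polymorphism study (gene genealogies)
#'
#' Each replicate simulates the default multi-species panel (both mating
#' types in every species), builds NJ genealogies from JC distances for the
#' STE3 gene and for background control genes, and classifies each tree's
#' clustering pattern.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param n_controls Control genes per replicate.
#' @return A tibble per replicate x gene: `rep`, `gene`, `is_ste3`,
#'   `pattern`.
#' @export
validate_trans_species <- function(n_reps = 20L, seed = 1L, n_controls = 4L) {
  rows <- map(seq_len(n_reps), function(k) {
    cfg <- sim_config(seed = child_seed(seed, 3000L + k))
    sim <- simulate_dataset(cfg)
    controls <- utils::head(
      grep("^bg", unique(sub("^[^.]*\\.", "", sim$annotations[[1L]]$gene_id)),
           value = TRUE), n_controls)
    genes <- c("STE3", controls)
    alleles <- collect_alleles_by_name(sim, genes)
    labels <- tibble(tip = sim$truth$strains$strain_id,
                     species = sim$truth$strains$species,
                     class = unname(ste3_type_of(sim$truth$strains$class)))
    bind_rows(map(genes, function(g) {
      sub <- alleles[alleles$gene == g, ]
      seqs <- setNames(sub$cds, sub$strain)
      D <- pairwise_distances(seqs, model = "JC")
      if (any(is.na(D$d))) {
        return(tibble(rep = k, gene = g, is_ste3 = g == "STE3",
                      pattern = "undefined"))
      }
      cl <- classify_clustering(nj_tree(D), labels)
      tibble(rep = k, gene = g, is_ste3 = g == "STE3", pattern = cl$pattern)
    }))
  })
  bind_rows(rows)
}

#' Composition-recovery study (MAT GC depression)
#'
#' Each replicate simulates a strain pair with the default planted GC
#' depression, computes 2-kb GC windows over the MAT contig and the
#' background contigs of one strain, and tests core-MAT windows against
#' background windows with the one-sided rank-sum test.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @return A tibble per replicate: `mat_gc`, `background_gc`, `p_value`,
#'   `detected`.
#' @export
validate_composition_recovery <- function(n_reps = 50L, seed = 1L) {
  rows <- map(seq_len(n_reps), function(k) {
    cfg <- sim_config(n_species = 1L, strains_per_species = c("A1", "A2"),
                      seed = child_seed(seed, 4000L + k))
    sim <- simulate_dataset(cfg)
    st <- names(sim$assemblies)[1L]
    asm <- sim$assemblies[[st]]
    core <- sim$truth$core_span
    track <- gc_windows(asm$seq[match(sim$truth$mat_contig, asm$id)])
    core_vals <- track$value[!track$partial & track$start >= core[1L] &
                               track$end <= core[2L]]
    bg_vals <- unlist(map(setdiff(asm$id, sim$truth$mat_contig), function(ct) {
      t2 <- gc_windows(asm$seq[match(ct, asm$id)])
      t2$value[!t2$partial]
    }))
    rs <- rank_sum_test(core_vals, bg_vals, alternative = "less")
    tibble(mat_gc = mean(core_vals), background_gc = mean(bg_vals),
           p_value = rs$p_value,
           detected = mean(core_vals) < mean(bg_vals) && rs$p_value < 0.05)
  })
  bind_rows(rows)
}

#' Suspension-bridge (breakpoint divergence) study
#'
#' Each replicate simulates an A1/A2 pair with within-inversion
#' homogenization planted, computes the 1-kb similarity track of the A1 MAT
#' contig against the A2 MAT contig, detects blocks, and runs the
#' breakpoint-versus-interior rank-sum test.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param homogenize Whether to plant interior homogenization.
#' @return A tibble per replicate: `p_value`, `n_breakpoint`, `n_interior`.
#' @export
validate_breakpoint_divergence <- function(n_reps = 20L, seed = 1L,
                                           homogenize = TRUE) {
  rows <- map(seq_len(n_reps), function(k) {
    cfg <- sim_config(n_species = 1L, strains_per_species = c("A1", "A2"),
                      homogenize_interior = homogenize,
                      n_background_contigs = 0L,
                      seed = child_seed(seed, 5000L + k))
    sim <- simulate_dataset(cfg)
    sts <- names(sim$assemblies)
    core <- sim$truth$core_span
    region_of <- function(st) {
      asm <- sim$assemblies[[st]]
      substring(asm$seq[match(sim$truth$mat_contig, asm$id)],
                core[1L] + 1L, core[2L])
    }
    mat_genes <- function(st) {
      ann <- sim$annotations[[st]]
      ann[ann$contig == sim$truth$mat_contig, ]
    }
    ga <- mat_genes(sts[1L]); gb <- mat_genes(sts[2L])
    anchors <- anchor_map(ga, strain_proteome(ga, sim$assemblies[[sts[1L]]]),
                          gb, strain_proteome(gb, sim$assemblies[[sts[2L]]]))
    blocks <- detect_blocks(anchors)
    # track in contig coordinates (compare corresponding core regions only)
    track <- window_similarity(region_of(sts[1L]), region_of(sts[2L]))
    track$start <- track$start + core[1L]
    track$end <- track$end + core[1L]
    res <- tryCatch(breakpoint_divergence_test(track, blocks),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(tibble(p_value = NA_real_, n_breakpoint = NA_integer_,
                    n_interior = NA_integer_))
    }
    tibble(p_value = res$p_value,
           n_breakpoint = attr(res, "n_breakpoint"),
           n_interior = attr(res, "n_interior"))
  })
  bind_rows(rows)
}
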