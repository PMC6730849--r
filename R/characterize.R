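#' Build a MAT reference panel from a simulated dataset
#'
#' Takes the MAT-role proteins of one strain per mating type: STE3 from both
#' an alpha-type and an a-type strain (labelled for allele typing), SXI1 and
#' SXI2 from strains that carry them, and the companion genes from the first
#' strain. In a real analysis the panel would come from well-annotated MAT
#' proteins of reference species; this constructor provides the equivalent
#' object for parameter-recovery validation.
#'
#' @param sim A `mat_sim` from [simulate_dataset()].
#' @return An amino-acid [seq_set()] with `role` and `class` columns.
#' @export
build_reference_panel <- function(sim) {
  strains <- sim$truth$strains
  take <- function(strain, roles) {
    prot <- strain_proteome(sim$annotations[[strain]], sim$assemblies[[strain]])
    ann <- sim$annotations[[strain]]
    sel <- ann$gene_id[ann$role %in% roles]
    out <- prot[prot$id %in% sel, ]
    out$role <- ann$role[match(out$id, ann$gene_id)]
    out
  }
  alpha_strain <- strains$strain_id[ste3_type_of(strains$class) == "alpha"][1L]
  a_strain <- strains$strain_id[ste3_type_of(strains$class) == "a"][1L]
  sxi1_strain <- strains$strain_id[hd_gene_of(strains$class) == "SXI1"][1L]
  sxi2_strain <- strains$strain_id[hd_gene_of(strains$class) == "SXI2"][1L]
  parts <- list()
  if (!is.na(alpha_strain)) {
    p <- take(alpha_strain, "STE3"); p$class <- "alpha"
    parts <- c(parts, list(p))
  }
  if (!is.na(a_strain)) {
    p <- take(a_strain, "STE3"); p$class <- "a"
    parts <- c(parts, list(p))
  }
  if (!is.na(sxi1_strain)) {
    p <- take(sxi1_strain, "SXI1"); p$class <- NA_character_
    parts <- c(parts, list(p))
  }
  if (!is.na(sxi2_strain)) {
    p <- take(sxi2_strain, "SXI2"); p$class <- NA_character_
    parts <- c(parts, list(p))
  }
  comp <- take(strains$strain_id[1L], COMPANION_ROLES)
  if (nrow(comp)) { comp$class <- NA_character_; parts <- c(parts, list(comp)) }
  panel <- bind_rows(parts)
  panel$id <- sprintf("%s|%s", panel$role,
                      ifelse(is.na(panel$class), "ref", panel$class))
  panel <- panel[!duplicated(panel$id), ]
  out <- seq_set(id = panel$id, seq = panel$seq, alphabet = "aa")
  out$role <- panel$role
  out$class <- panel$class
  out
}

#' Read a MAT reference panel from FASTA
#'
#' Panel FASTA headers carry `role=` and optional `class=` tags in the
#' description, e.g. `>STE3_ref1 role=STE3 class=alpha`. A small synthetic
#' panel generated by [build_reference_panel()] ships with the package:
#' `system.file("extdata", "synthetic_mat_panel.fasta", package = "matloci")`.
#'
#' @param path Path to the panel FASTA.
#' @return An amino-acid [seq_set()] with `role` and `class` columns.
#' @export
read_panel_fasta <- function(path) {
  panel <- read_fasta(path, alphabet = "aa")
  tag <- function(x, key) {
    m <- regmatches(x, regexec(paste0(key, "=([^ ]+)"), x))
    vapply(m, function(v) if (length(v) == 2L) v[2L] else NA_character_,
           character(1))
  }
  panel$role <- tag(panel$desc, "role")
  panel$class <- tag(panel$desc, "class")
  if (all(is.na(panel$role))) abort("panel headers carry no role= tags")
  panel
}

#' Characterize one strain: pheromone scan, roles, MAT locus, allele
#'
#' @param annotation,assembly The strain's gene models and contigs.
#' @param panel A reference panel (see [build_reference_panel()]).
#' @param flank Companion-gene flank for [locate_mat()].
#' @return A list: `pheromone_hits`, `roles`, `ste3_typing`, `report`
#'   (the [locate_mat()] row, allele classified).
#' @export
characterize_strain <- function(annotation, assembly, panel, flank = 20000L) {
  if (is.null(panel) || nrow(panel) == 0L) abort("reference panel required")
  hits <- scan_pheromones(assembly)
  proteome <- strain_proteome(annotation, assembly)
  roles <- assign_roles(proteome, panel[is.na(panel$class) | panel$class %in% c("a", "alpha"), ])
  # The consensus is permissive enough that long assemblies carry chance ORF
  # matches; the MAT pheromone gene is taken as the hit nearest the STE3
  # gene on its contig (pheromone and receptor are adjacent at the P/R end).
  mf_gene <- NA_character_
  mf_hit <- NULL
  ste3_gene_id <- roles$gene_id[roles$role == "STE3"]
  if (nrow(hits) > 0L) {
    cand <- hits
    if (length(ste3_gene_id) == 1L && !is.na(ste3_gene_id)) {
      sg <- annotation[match(ste3_gene_id, annotation$gene_id), ]
      cand <- cand[cand$contig == sg$contig, ]
      if (nrow(cand) > 0L) {
        gap <- pmax(pmax(sg$start - cand$end, cand$start - sg$end), 0L)
        cand <- cand[which.min(gap), ]
      }
    } else {
      cand <- cand[1L, ]
    }
    if (nrow(cand) == 1L) {
      mf_hit <- cand
      ov <- annotation$contig == cand$contig &
        annotation$start < cand$end & annotation$end > cand$start
      if (any(ov)) mf_gene <- annotation$gene_id[which(ov)[1L]]
    }
  }
  roles <- bind_rows(roles,
                     tibble(role = "MF", gene_id = mf_gene, score = NA_real_,
                            second_best_score = NA_real_, identity = NA_real_,
                            flag = "unique", assigned = !is.na(mf_gene)))
  ste3_id <- roles$gene_id[roles$role == "STE3"]
  ste3_typing <- NULL
  ste3_type <- NULL
  if (length(ste3_id) == 1L && !is.na(ste3_id)) {
    refs <- panel[!is.na(panel$class), ]
    if (nrow(refs) > 0L && all(c("a", "alpha") %in% refs$class)) {
      q <- proteome$seq[match(ste3_id, proteome$id)]
      ste3_typing <- type_ste3(q, refs)
      if (ste3_typing$type != "unresolved") ste3_type <- ste3_typing$type
    }
  }
  report <- locate_mat(annotation, roles, ste3_type = ste3_type, flank = flank)
  list(pheromone_hits = hits, mf_hit = mf_hit, roles = roles,
       ste3_typing = ste3_typing, report = report)
}

#' Collect allele sequences of reference genes across strains
#'
#' For each reference gene, the best-scoring protein (global alignment) in
#' every other strain is taken as its allele, subject to a reciprocal-best
#' check within the reference gene set.
#'
#' @param annotations,assemblies Named lists (one element per strain).
#' @param ref_strain Strain id providing the reference genes.
#' @param ref_genes Character vector of reference gene ids.
#' @param scheme Protein [scoring_scheme()].
#' @return A tibble: `gene` (reference gene id), `strain`, `gene_id`, `cds`.
#' @export
collect_alleles <- function(annotations, assemblies, ref_strain, ref_genes,
                            scheme = scoring_scheme("aa")) {
  ref_ann <- annotations[[ref_strain]]
  ref_prot <- strain_proteome(ref_ann, assemblies[[ref_strain]])
  refs <- ref_prot[ref_prot$id %in% ref_genes, ]
  if (nrow(refs) == 0L) abort("no reference genes found")
  cds_of <- function(strain, gene_id) {
    ann <- annotations[[strain]]
    gene_cds(ann[match(gene_id, ann$gene_id), ], assemblies[[strain]])
  }
  rows <- list(tibble(gene = refs$id, strain = ref_strain, gene_id = refs$id,
                      cds = map_chr(refs$id, ~ cds_of(ref_strain, .x))))
  for (st in setdiff(names(annotations), ref_strain)) {
    prot <- strain_proteome(annotations[[st]], assemblies[[st]])
    S <- align_score_matrix(refs, prot, scheme)        # refs x queries
    best_q <- max.col(S, ties.method = "first")
    # reciprocity within the reference set
    back <- max.col(t(S[, best_q, drop = FALSE]), ties.method = "first")
    for (i in seq_len(nrow(refs))) {
      if (back[i] != i) next
      gid <- prot$id[best_q[i]]
      rows[[length(rows) + 1L]] <- tibble(gene = refs$id[i], strain = st,
                                          gene_id = gid,
                                          cds = cds_of(st, gid))
    }
  }
  bind_rows(rows)
}

#' Per-gene divergence analysis of a strain trio
#'
#' Mirrors the three-strain comparison used to test for recombination
#' suppression: per-gene dS between the odd strain and a shared reference
#' strain (between mating types) versus dS between the two same-class
#' strains (within mating type), a one-sided t-test of those two sets, and
#' closest-pair similarity calls. Genes whose role defines the mating type
#' (MF, STE3, SXI) are excluded from the t-test gene set.
#'
#' @param annotations,assemblies Named lists covering the three strains.
#' @param classes Named character vector strain -> allele class; exactly one
#'   class must appear once and one twice.
#' @param genes Reference gene ids (from the shared strain) to analyse; when
#'   `NULL`, all genes within the shared strain's annotated core MAT contig
#'   are used.
#' @param bootstrap_B Bootstrap replicates for per-gene SEs (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return A list: `ds_table` (per gene x comparison), `calls`
#'   (closest-pair calls), `ttest` (a `matloci_ttest`), `ref_strain`.
#' @export
trio_divergence <- function(annotations, assemblies, classes, genes = NULL,
                            bootstrap_B = 0L, seed = 1L) {
  stopifnot(length(classes) == 3L)
  tab <- table(classes)
  if (!setequal(as.integer(tab), c(1L, 2L))) {
    abort("classes must be one strain of one class and two of another")
  }
  dup_class <- names(tab)[tab == 2L]
  odd_strain <- names(classes)[classes != dup_class]
  dup_strains <- names(classes)[classes == dup_class]
  ref_strain <- dup_strains[2L]  # shared comparator (UJ1-like)
  other_dup <- dup_strains[1L]

  ref_ann <- annotations[[ref_strain]]
  if (is.null(genes)) genes <- ref_ann$gene_id
  alleles <- collect_alleles(annotations, assemblies, ref_strain, genes)
  roles <- setNames(ref_ann$role, ref_ann$gene_id)

  ds_rows <- list()
  for (g in unique(alleles$gene)) {
    sub <- alleles[alleles$gene == g, ]
    ref_cds <- sub$cds[sub$strain == ref_strain]
    for (st in c(odd_strain, other_dup)) {
      cds <- sub$cds[sub$strain == st]
      if (length(cds) != 1L || length(ref_cds) != 1L) next
      est <- tryCatch(
        estimate_ds(codon_align(cds, ref_cds, name_a = st, name_b = ref_strain),
                    bootstrap_B = bootstrap_B, seed = seed),
        error = function(e) NULL)
      if (is.null(est)) next
      ds_rows[[length(ds_rows) + 1L]] <- mutate(
        est, gene = g, role = unname(roles[g]),
        pair = paste(st, ref_strain, sep = "|"),
        comparison = if (st == odd_strain) "between" else "within",
        .before = 1L)
    }
  }
  ds_table <- bind_rows(ds_rows)

  labels <- classes
  calls <- closest_pair_calls(
    alleles |> filter(.data$strain %in% names(classes)) |>
      select("gene", "strain", "cds"),
    labels)

  test_genes <- ds_table |>
    filter(!(.data$role %in% c("MF", "STE3", "SXI1", "SXI2"))) |>
    tidyr::pivot_wider(id_cols = "gene", names_from = "comparison",
                       values_from = "dS") |>
    filter(!is.na(.data$between), !is.na(.data$within))
  ttest <- if (nrow(test_genes) >= 2L) {
    compare_ds_sets(test_genes$between, test_genes$within)
  } else NULL
  list(ds_table = ds_table, calls = calls, ttest = ttest,
       ref_strain = ref_strain, odd_strain = odd_strain)
}

#' Format a dS table for output ("Un" marks undefined estimates)
#' @param ds_table A tibble from [trio_divergence()].
#' @return A tibble with display columns.
#' @export
format_ds_table <- function(ds_table) {
  ds_table |>
    mutate(dS_print = ifelse(.data$status == "undefined", "Un",
                             sprintf("%.4f", .data$dS))) |>
    select("gene", "role", "pair", "comparison", "dS_print", "SE_dS",
           "dN", "SE_dN", "status")
}

#' Run the full characterization pipeline
#'
#' Orchestrates the analyses over a simulated (or loaded) strain panel:
#' pheromone scan, role assignment, MAT-locus detection and allele
#' classification per strain; synteny and inversion detection plus a
#' similarity track between the first strains of the two mating types; GC
#' composition contrasts; trio divergence when the panel contains a
#' one-plus-two class trio within one species; and genealogy classification
#' of STE3 and background control genes. Identical input and seed give
#' identical results.
#'
#' @param sim A `mat_sim` (or a list with `assemblies`, `annotations` and
#'   optionally `truth`).
#' @param panel Reference panel; defaults to [build_reference_panel()] when
#'   truth is available.
#' @param seed Seed recorded in, and used by, stochastic stages.
#' @return A `mat_report` list; see the individual elements.
#' @export
run_characterize <- function(sim, panel = NULL, seed = 1L) {
  if (is.null(panel)) {
    if (is.null(sim$truth)) abort("reference panel required")
    panel <- build_reference_panel(sim)
  }
  strains <- names(sim$assemblies)
  per_strain <- map(strains, function(st) {
    characterize_strain(sim$annotations[[st]], sim$assemblies[[st]], panel)
  })
  names(per_strain) <- strains
  reports <- bind_rows(map(per_strain, "report"))
  hits <- bind_rows(imap(per_strain, ~ mutate(.x$pheromone_hits, strain = .y,
                                              .before = 1L)))

  # synteny between the first strains of the two mating types, on MAT genes
  synteny <- NULL
  alleles <- reports$allele
  a1 <- strains[which(alleles %in% c("A1", "A1*"))[1L]]
  a2 <- strains[which(alleles %in% c("A2", "A2*"))[1L]]
  if (!is.na(a1) && !is.na(a2)) {
    synteny <- mat_region_synteny(sim, per_strain, a1, a2)
  }

  composition <- composition_contrast(sim, reports)

  divergence <- NULL
  cls <- setNames(reports$allele, reports$genome_id)
  cls <- cls[!is.na(cls) & cls != "unresolved"]
  if (length(cls) >= 3L) {
    trio <- find_class_trio(cls)
    if (!is.null(trio)) {
      dup_cls <- names(which(table(trio) == 2L))[1L]
      ref_strain <- names(trio)[trio == dup_cls][2L]
      core <- core_gene_set(sim, reports, ref_strain)
      divergence <- trio_divergence(sim$annotations[names(trio)],
                                    sim$assemblies[names(trio)], trio,
                                    genes = core, seed = seed)
    }
  }

  genealogy <- genealogy_screen(sim, reports, seed = seed)

  structure(list(pheromone_hits = hits, reports = reports,
                 per_strain = per_strain, synteny = synteny,
                 composition = composition, divergence = divergence,
                 genealogy = genealogy, seed = seed,
                 panel_ids = panel$id), class = "mat_report")
}

# pick three strains forming a 1+2 class trio (same species when possible)
find_class_trio <- function(cls) {
  tab <- table(cls)
  dup <- names(tab)[tab >= 2L][1L]
  odd <- names(tab)[tab >= 1L & names(tab) != dup][1L]
  if (is.na(dup) || is.na(odd)) return(NULL)
  sel <- c(names(cls)[cls == odd][1L], names(cls)[cls == dup][1:2])
  setNames(cls[sel], sel)
}

core_gene_set <- function(sim, reports, strain) {
  rep <- reports[reports$genome_id == strain, ]
  ann <- sim$annotations[[strain]]
  if (is.na(rep$core_start)) return(ann$gene_id)
  ann$gene_id[ann$contig == rep$contig &
                ann$start >= rep$core_start & ann$end <= rep$core_end]
}

mat_region_synteny <- function(sim, per_strain, a1, a2) {
  region_genes <- function(st) {
    rep <- per_strain[[st]]$report
    ann <- sim$annotations[[st]]
    ann[ann$contig == rep$contig, ]
  }
  ga <- region_genes(a1); gb <- region_genes(a2)
  pa <- strain_proteome(ga, sim$assemblies[[a1]])
  pb <- strain_proteome(gb, sim$assemblies[[a2]])
  anchors <- anchor_map(ga, pa, gb, pb)
  blocks <- detect_blocks(anchors)
  # similarity track over the corresponding core MAT regions (plus a small
  # flank), in A-strain contig coordinates
  repa <- per_strain[[a1]]$report
  repb <- per_strain[[a2]]$report
  core_region <- function(rep, asm) {
    s <- asm$seq[match(rep$contig, asm$id)]
    lo <- max(rep$core_start - 5000L, 0L)
    hi <- min(rep$core_end + 5000L, nchar(s))
    list(seq = substring(s, lo + 1L, hi), offset = lo)
  }
  qa <- core_region(repa, sim$assemblies[[a1]])
  qb <- core_region(repb, sim$assemblies[[a2]])
  track <- window_similarity(qa$seq, qb$seq)
  track$start <- track$start + qa$offset
  track$end <- track$end + qa$offset
  list(strain_a = a1, strain_b = a2, anchors = anchors, blocks = blocks,
       track = track)
}

composition_contrast <- function(sim, reports) {
  rows <- list(); tests <- list()
  for (st in reports$genome_id) {
    rep <- reports[reports$genome_id == st, ]
    if (is.na(rep$contig)) next
    asm <- sim$assemblies[[st]]
    mat_seq <- asm$seq[match(rep$contig, asm$id)]
    track <- gc_windows(mat_seq)
    core_w <- !track$partial & track$start >= rep$core_start &
      track$end <= rep$core_end
    bg_ids <- setdiff(asm$id, rep$contig)
    bg_vals <- unlist(map(bg_ids, function(ct) {
      t2 <- gc_windows(asm$seq[match(ct, asm$id)])
      t2$value[!t2$partial]
    }))
    test <- if (sum(core_w) >= 2L && length(bg_vals) >= 2L) {
      rank_sum_test(track$value[core_w], bg_vals, alternative = "less")
    } else NULL
    rows[[st]] <- tibble(strain = st, mat_gc = mean(track$value[core_w]),
                         background_gc = if (length(bg_vals)) mean(bg_vals)
                           else NA_real_,
                         p_value = if (is.null(test)) NA_real_ else test$p_value)
    tests[[st]] <- test
  }
  list(summary = bind_rows(rows), tests = tests)
}

#' Genealogy screen: STE3 versus background control genes
#'
#' Collects alleles of STE3 and of background control genes across all
#' strains, builds neighbor-joining trees from JC distances and classifies
#' each tree's clustering pattern.
#'
#' @param sim A `mat_sim`-like list.
#' @param reports The per-strain [locate_mat()] table (for roles); may be
#'   `NULL` when `sim$truth` is available.
#' @param n_controls Number of background control genes.
#' @param seed Unused placeholder for interface symmetry.
#' @return A tibble: `gene`, `role`, `pattern`; trees in attribute `trees`.
#' @export
genealogy_screen <- function(sim, reports = NULL, n_controls = 4L, seed = 1L) {
  strains <- names(sim$annotations)
  ref <- strains[[1L]]
  ann <- sim$annotations[[ref]]
  ste3 <- ann$gene_id[!is.na(ann$role) & ann$role == "STE3"]
  controls <- ann$gene_id[ann$contig != ann$contig[match(ste3[1L], ann$gene_id)]]
  controls <- utils::head(controls, n_controls)
  genes <- c(ste3[1L], controls)
  alleles <- collect_alleles(sim$annotations, sim$assemblies, ref, genes)
  labels <- if (!is.null(sim$truth)) {
    tibble(tip = sim$truth$strains$strain_id,
           species = sim$truth$strains$species,
           class = ste3_type_of(sim$truth$strains$class))
  } else {
    tibble(tip = reports$genome_id,
           species = sub("_.*$", "", reports$genome_id),
           class = ifelse(reports$allele %in% c("A1", "A1*"), "alpha", "a"))
  }
  trees <- list(); rows <- list()
  for (g in genes) {
    sub <- alleles[alleles$gene == g, ]
    if (nrow(sub) < 3L) next
    seqs <- setNames(sub$cds, sub$strain)
    # substitution-only data: equal lengths expected; skip otherwise
    if (length(unique(nchar(seqs))) != 1L) next
    D <- pairwise_distances(seqs, model = "JC")
    if (any(is.na(D$d))) next
    tr <- nj_tree(D)
    cl <- classify_clustering(tr, labels[labels$tip %in% names(seqs), ])
    trees[[g]] <- tr
    rows[[g]] <- tibble(gene = g,
                        role = ann$role[match(g, ann$gene_id)] %||% NA_character_,
                        pattern = cl$pattern)
  }
  out <- bind_rows(rows)
  attr(out, "trees") <- trees
  out
}

#' Write a report bundle to disk
#'
#' Emits TSV tables, BED/GFF3 tracks, Newick trees and a JSON run summary.
#'
#' @param report A `mat_report` from [run_characterize()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(report$pheromone_hits, "pheromone_hits.tsv")
  tsv(select(report$reports, -"companions"), "mat_reports.tsv")
  if (!is.null(report$synteny)) {
    tsv(report$synteny$anchors, "anchors.tsv")
    tsv(select(report$synteny$blocks$blocks, -"genes"), "blocks.tsv")
    tsv(report$synteny$track, "similarity_track.tsv")
  }
  tsv(report$composition$summary, "composition.tsv")
  if (!is.null(report$divergence)) {
    tsv(format_ds_table(report$divergence$ds_table), "ds_table.tsv")
    tsv(report$divergence$calls, "closest_pair_calls.tsv")
  }
  if (!is.null(report$genealogy)) {
    tsv(report$genealogy, "genealogy_patterns.tsv")
    trees <- attr(report$genealogy, "trees")
    if (length(trees)) {
      writeLines(unlist(map(trees, write_newick)), file.path(dir, "trees.nwk"))
    }
  }
  ok <- reports_bed(report)
  if (!is.null(ok)) write_bed(ok, file.path(dir, "core_mat.bed"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    summary <- list(
      seed = report$seed,
      n_strains = nrow(report$reports),
      alleles = setNames(as.list(report$reports$allele),
                         report$reports$genome_id),
      inverted_blocks = if (!is.null(report$synteny)) {
        sum(report$synteny$blocks$blocks$orientation == "inverted")
      } else NA,
      ttest_p = if (!is.null(report$divergence$ttest)) {
        report$divergence$ttest$p_value
      } else NA)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

reports_bed <- function(report) {
  ok <- report$reports[!is.na(report$reports$core_start), ]
  if (nrow(ok) == 0L) return(NULL)
  as_bed(tibble(contig = ok$contig, start = ok$core_start, end = ok$core_end,
                gene_id = paste0(ok$genome_id, ".coreMAT"),
                strand = rep(".", nrow(ok))))
}

#' Read a flat key=value pipeline configuration file
#'
#' Sections are `[name]` headers; values are typed (numbers and TRUE/FALSE
#' recognized). Unknown sections are kept as-is.
#'
#' @param path Path to the config file.
#' @return A nested named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  out <- list(); section <- "global"
  for (ln in lines) {
    ln <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(sprintf("malformed config line '%s' (expected key=value)", ln))
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else val
    out[[section]][[key]] <- parsed
  }
  out
}
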