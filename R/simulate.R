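#' Default core-MAT gene template
#'
#' Gene order of the ancestral (A1-orientation) fused MAT region: the
#' pheromone precursor (MF) and pheromone receptor (STE3) at one end, the
#' homeodomain (SXI) gene at the other, with the conserved companions STE20,
#' IKS1, STE11, MYO2 and RPL22 plus filler genes in between. Lengths include
#' the stop codon; the filler length is set so the expected gap between the
#' STE3 and SXI genes (with intergenic gaps drawn uniform on `gap_range`)
#' is about 55 kb.
#'
#' @return A tibble with columns `name`, `role`, `length`, `strand`.
#' @export
default_mat_template <- function() {
  named <- tibble(
    name = c("MF", "STE3", "STE20", "IKS1", "STE11", "MYO2", "RPL22"),
    role = c("MF", "STE3", "STE20", "IKS1", "STE11", "MYO2", "RPL22"),
    length = c(NA_integer_, 1275L, 2100L, 1800L, 1998L, 2400L, 900L),
    strand = c("+", "-", "+", "+", "-", "+", "-"))
  fillers <- tibble(
    name = sprintf("fil%02d", 1:14),
    role = "other",
    length = NA_integer_,  # drawn uniform on 900-2400 nt at simulation time
    strand = rep(c("+", "-"), length.out = 14))
  hd <- tibble(name = "SXI", role = "HD", length = 1200L, strand = "+")
  bind_rows(named, fillers, hd)
}

#' Simulation configuration
#'
#' Defines the conditions of a synthetic multi-strain dataset: a panel of
#' haploid strains, each carrying one fused MAT region whose allele class
#' (A1/A2/A1*/A2*) sets its STE3 allele, its HD gene (SXI1 or SXI2) and its
#' gene order (A2-type orders differ from A1 by the planted inversions).
#'
#' @param n_species Number of species (>= 1).
#' @param strains_per_species Character vector (recycled across species) or
#'   list of vectors of allele classes, e.g. `c("A1", "A2")`.
#' @param tree_height Species-tree root height, substitutions/site.
#' @param within_species_depth Branch length from a species tip to each of
#'   its strains, substitutions/site.
#' @param ste3_allele_depth Divergence depth of the two STE3 allele classes,
#'   substitutions/site; must exceed `tree_height + within_species_depth`
#'   for trans-specific allele trees.
#' @param background_gc,mat_gc Equilibrium GC of the genomic background and
#'   of the core MAT region.
#' @param mat_suppression_extra Extra divergence (substitutions/site) planted
#'   between mating types, confined to the core MAT region.
#' @param homogenize_interior If `TRUE`, sites deeper than `edge_zone` inside
#'   a planted inversion receive only `interior_factor` times the extra
#'   divergence, mimicking gene-conversion-like homogenization and producing
#'   the suspension-bridge similarity pattern.
#' @param interior_factor,edge_zone See `homogenize_interior`.
#' @param kappa HKY transition/transversion ratio.
#' @param template Gene template tibble (see [default_mat_template()]).
#' @param inversion_segments List of 1-based gene-index intervals `c(from, to)`
#'   reversed in A2-type alleles; default two, one spanning most of the core
#'   region.
#' @param gap_range Intergenic gap range (nt), drawn uniformly.
#' @param mf_spacer Pheromone spacer length in [15, 60], or `NA` to draw it.
#' @param flank_len Non-MAT flank length on each side of the MAT region.
#' @param n_background_contigs,background_contig_len,background_genes_per_contig
#'   Background genome content (non-MAT contigs carrying control genes).
#' @param background_gene_len Length of each background CDS (nt, incl. stop).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 3L,
                       strains_per_species = c("A1", "A2"),
                       tree_height = 0.2,
                       within_species_depth = 0.005,
                       ste3_allele_depth = 0.5,
                       background_gc = 0.60,
                       mat_gc = background_gc - 0.08,
                       mat_suppression_extra = 0.02,
                       homogenize_interior = FALSE,
                       interior_factor = 0.25,
                       edge_zone = 3000L,
                       kappa = 2.0,
                       template = default_mat_template(),
                       inversion_segments = list(c(3L, 17L), c(19L, 21L)),
                       gap_range = c(200L, 2000L),
                       mf_spacer = NA_integer_,
                       flank_len = 8000L,
                       n_background_contigs = 2L,
                       background_contig_len = 25000L,
                       background_genes_per_contig = 4L,
                       background_gene_len = 1500L,
                       seed = 1L) {
  if (n_species < 1L) abort("n_species must be >= 1")
  if (!(background_gc > 0 && background_gc < 1) || !(mat_gc > 0 && mat_gc < 1)) {
    abort("GC fractions must lie strictly between 0 and 1")
  }
  if (!is.list(strains_per_species)) {
    strains_per_species <- rep(list(strains_per_species), n_species)
  }
  strains_per_species <- rep_len(strains_per_species, n_species)
  known <- c("A1", "A2", "A1*", "A2*")
  bad <- setdiff(unlist(strains_per_species), known)
  if (length(bad) > 0L) abort(sprintf("unknown allele class '%s'", bad[[1L]]))
  n_genes <- nrow(template)
  for (seg in inversion_segments) {
    if (length(seg) != 2L || seg[1L] > seg[2L] || seg[1L] < 1L || seg[2L] > n_genes) {
      abort("each inversion segment must be c(from, to) within the template")
    }
  }
  check_segments_disjoint(inversion_segments)
  if (ste3_allele_depth <= tree_height + within_species_depth) {
    warn("ste3_allele_depth does not exceed the strain-tree height; STE3 allele trees will not be trans-specific")
  }
  structure(list(
    n_species = as.integer(n_species),
    strains_per_species = strains_per_species,
    tree_height = tree_height,
    within_species_depth = within_species_depth,
    ste3_allele_depth = ste3_allele_depth,
    background_gc = background_gc, mat_gc = mat_gc,
    mat_suppression_extra = mat_suppression_extra,
    homogenize_interior = homogenize_interior,
    interior_factor = interior_factor, edge_zone = as.integer(edge_zone),
    kappa = kappa, template = template,
    inversion_segments = inversion_segments,
    gap_range = as.integer(gap_range), mf_spacer = mf_spacer,
    flank_len = as.integer(flank_len),
    n_background_contigs = as.integer(n_background_contigs),
    background_contig_len = as.integer(background_contig_len),
    background_genes_per_contig = as.integer(background_genes_per_contig),
    background_gene_len = as.integer(background_gene_len),
    seed = as.integer(seed)), class = "sim_config")
}

check_segments_disjoint <- function(segments) {
  if (length(segments) < 2L) return(invisible(TRUE))
  m <- do.call(rbind, segments)
  m <- m[order(m[, 1L]), , drop = FALSE]
  if (any(m[-1L, 1L] <= m[-nrow(m), 2L])) abort("inversion segments overlap")
  invisible(TRUE)
}

#' Simulate a species tree (Yule process)
#'
#' Pure-birth topology with exponential waiting times, rescaled so the root
#' is at the requested height; tips are labelled `sp1..spN`.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed.
#' @param height Root height in substitutions/site.
#' @return An ultrametric `ape::phylo` tree.
#' @export
simulate_species_tree <- function(n_species, seed = 1L, height = 1) {
  if (n_species < 2L) abort("n_species must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  tr$tip.label <- sub("^t", "sp", tr$tip.label)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr
}

# Strain tree: species tips replaced by stars of their strains, each on a
# branch of `within_depth`. For one species the tree is a plain star.
build_strain_tree <- function(species_tree, strains, within_depth) {
  star <- function(ids) paste0("(", paste0(ids, ":", format(within_depth, scientific = FALSE), collapse = ","), ")")
  if (is.null(species_tree)) {
    nw <- paste0(star(strains$strain_id), ";")
    return(read_newick(nw))
  }
  nw <- write_newick(species_tree)
  for (sp in unique(strains$species)) {
    ids <- strains$strain_id[strains$species == sp]
    if (length(ids) > 1L) {
      nw <- sub(paste0(sp, ":"), paste0(star(ids), ":"), nw, fixed = TRUE)
    } else {
      # single strain: extend the species branch
      m <- regmatches(nw, regexec(paste0(sp, ":([0-9.eE+-]+)"), nw))[[1L]]
      len <- as.numeric(m[2L]) + within_depth
      nw <- sub(m[1L], paste0(ids, ":", format(len, scientific = FALSE)), nw, fixed = TRUE)
    }
  }
  read_newick(nw)
}

#' Generate a pheromone-precursor CDS matching the consensus
#'
#' Builds a CDS whose translation is `M + spacer + C + two residues from
#' {I,L,M,V,S,T} + one residue`, followed by a stop codon, i.e. a CaaX-box
#' terminated lipopeptide pheromone precursor. Codons are drawn with
#' probability proportional to their equilibrium weight at `gc`.
#'
#' @param spacer_len Spacer length in residues, between 15 and 60.
#' @param seed Integer seed.
#' @param gc Codon-bias GC fraction.
#' @return A nucleotide CDS string (length `3 * (spacer_len + 6)` nt,
#'   including the stop codon).
#' @export
make_pheromone_gene <- function(spacer_len, seed = 1L, gc = 0.5) {
  if (spacer_len < 15L || spacer_len > 60L) {
    abort(sprintf("spacer length %d outside [15, 60]", spacer_len))
  }
  ci <- codon_info()
  aas <- sort(unique(ci$aa))
  with_seed(seed, {
    spacer <- paste(sample(aas, spacer_len, replace = TRUE), collapse = "")
    box <- paste(sample(c("I", "L", "M", "V", "S", "T"), 2L, replace = TRUE),
                 collapse = "")
    last <- sample(aas, 1L)
    peptide <- paste0("M", spacer, "C", box, last)
    cds <- paste(reverse_translate(peptide, gc), collapse = "")
    stop_codon <- sample(ci$stops, 1L, prob = codon_weights(ci$stops, gc))
    paste0(cds, stop_codon)
  })
}

#' Apply inversion segments to a gene template
#'
#' Each segment `c(from, to)` (1-based gene indices, inclusive) has its genes
#' reversed in order and flipped in strand; genes outside are untouched.
#' Applying the same segment twice restores the input.
#'
#' @param template A tibble with at least a `strand` column, one row per gene
#'   in order.
#' @param segments List of index intervals; must be non-overlapping and
#'   within the template.
#' @return The rearranged template, with an `orig_index` column giving each
#'   row's position in the input.
#' @export
apply_inversions <- function(template, segments) {
  n <- nrow(template)
  out <- template
  if (!("orig_index" %in% names(out))) out$orig_index <- seq_len(n)
  for (seg in segments) {
    if (length(seg) != 2L || seg[1L] > seg[2L] || seg[1L] < 1L || seg[2L] > n) {
      abort("segment out of template range")
    }
  }
  check_segments_disjoint(segments)
  for (seg in segments) {
    idx <- seg[1L]:seg[2L]
    out[idx, ] <- out[rev(idx), ]
    out$strand[idx] <- c("+" = "-", "-" = "+")[out$strand[idx]]
  }
  out
}

ste3_type_of <- function(class) {
  c("A1" = "alpha", "A1*" = "alpha", "A2" = "a", "A2*" = "a")[class]
}
hd_gene_of <- function(class) {
  c("A1" = "SXI2", "A1*" = "SXI1", "A2" = "SXI1", "A2*" = "SXI2")[class]
}
# Whether a class carries the A2-type (inverted) gene order.
inverted_order <- function(class) ste3_type_of(class) == "a"

# Lay out the MAT contig: flank + genes/gaps + flank, 0-based half-open
# coordinates in ancestral (A1) orientation.
sim_layout <- function(config) {
  tpl <- config$template
  n <- nrow(tpl)
  na_len <- which(is.na(tpl$length))
  if (length(na_len) > 0L) {
    tpl$length[na_len] <- 3L * sample(300:800, length(na_len), replace = TRUE)
  }
  gaps <- as.integer(round(stats::runif(n - 1L, config$gap_range[1L],
                                        config$gap_range[2L])))
  starts <- integer(n); ends <- integer(n)
  pos <- config$flank_len
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + tpl$length[i]
    pos <- ends[i] + if (i < n) gaps[i] else 0L
  }
  region_end <- ends[n]
  list(genes = mutate(tpl, start = starts, end = ends, orig_index = seq_len(n)),
       gaps = gaps,
       core_start = starts[1L], core_end = region_end,
       contig_len = region_end + config$flank_len)
}

# Inversion segment boundaries in contig coordinates: each segment spans from
# the midpoint of the gap before its first gene to the midpoint of the gap
# after its last gene. Breakpoint intervals are those bounding gaps.
segment_bounds <- function(layout, segments) {
  g <- layout$genes
  mid_before <- function(i) {
    if (i == 1L) g$start[1L] else (g$end[i - 1L] + g$start[i]) %/% 2L
  }
  mid_after <- function(i) {
    if (i == nrow(g)) g$end[i] else (g$end[i] + g$start[i + 1L]) %/% 2L
  }
  map(segments, function(seg) {
    list(genes = seg,
         lo = mid_before(seg[1L]), hi = mid_after(seg[2L]),
         bp_left = c(if (seg[1L] == 1L) g$start[1L] else g$end[seg[1L] - 1L],
                     g$start[seg[1L]]),
         bp_right = c(g$end[seg[2L]],
                      if (seg[2L] == nrow(g)) g$end[seg[2L]] else g$start[seg[2L] + 1L]))
  })
}

# Mirror an interval [s, e) within segment [lo, hi).
mirror_interval <- function(s, e, lo, hi) c(lo + (hi - e), lo + (hi - s))

evolve_part <- function(root_seq, tree, gc, kappa, cds_map = NULL) {
  tips <- evolve_tree_idx(nt_to_idx(root_seq), tree, hky_model(gc, kappa),
                          cds_map = cds_map)
  vapply(tips, idx_to_nt, character(1))
}

# Class-split evolution: the part's root evolves along two independent
# branches (one per mating type), optionally with a per-site rate mask, then
# each class root evolves along the full strain tree. Returns tip sequences
# for strains of the requested class per tip.
evolve_class_split <- function(root_seq, tree, gc, kappa, extra_by_class,
                               site_scale = NULL, cds_map = NULL) {
  model <- hky_model(gc, kappa)
  root_idx <- nt_to_idx(root_seq)
  out <- list()
  for (cl in names(extra_by_class)) {
    t_eff <- extra_by_class[[cl]]
    tvec <- if (is.null(site_scale)) t_eff else t_eff * site_scale
    class_root <- if (all(tvec <= 0)) root_idx else {
      repair_stops(root_idx, evolve_branch_idx(root_idx, tvec, model), cds_map)
    }
    tips <- evolve_tree_idx(class_root, tree, model, cds_map = cds_map)
    out[[cl]] <- vapply(tips, idx_to_nt, character(1))
  }
  out
}

#' Simulate a multi-strain dataset with fused MAT regions
#'
#' For each strain the simulator produces one MAT-bearing contig (flanks at
#' background GC, core MAT region at `mat_gc`) and background contigs with
#' control genes. A1-type strains carry the template gene order; A2-type
#' strains carry the order produced by [apply_inversions()] with the
#' configured segments (segments are reverse-complemented at the nucleotide
#' level, so coordinates stay exact). STE3 alleles descend from a two-allele
#' gene tree of depth `ste3_allele_depth`; SXI1 and SXI2 are distinct genes
#' assigned by allele class; `mat_suppression_extra` adds divergence between
#' mating types confined to the core MAT region. The pheromone CDS is planted
#' per mating type and held fixed (the consensus motif is treated as a hard
#' constraint).
#'
#' @param config A [sim_config()].
#' @return A `mat_sim` list with elements `assemblies` (named list of
#'   [seq_set()] per strain), `annotations` (named list of gene-model
#'   tibbles), and `truth` (planted parameters, coordinates, classes, trees).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed

  # strain panel
  strains <- bind_rows(map(seq_len(config$n_species), function(i) {
    cls <- config$strains_per_species[[i]]
    tibble(species = sprintf("sp%d", i), class = cls,
           strain_id = sprintf("sp%d_%s_%d", i, sub("\\*", "s", cls), seq_along(cls)))
  }))

  species_tree <- if (config$n_species >= 2L) {
    simulate_species_tree(config$n_species, seed = child_seed(seed, 1L),
                          height = config$tree_height)
  } else NULL
  strain_tree <- build_strain_tree(species_tree, strains,
                                   config$within_species_depth)

  with_seed(child_seed(seed, 2L), {
    # --- layout and ancestral parts -------------------------------------
    spacer <- if (is.na(config$mf_spacer)) sample(15:60, 1L) else config$mf_spacer
    mf_len <- 3L * (spacer + 6L)
    config$template$length[config$template$role == "MF"] <- mf_len
    layout <- sim_layout(config)
    segs <- segment_bounds(layout, config$inversion_segments)
    genes <- layout$genes

    mf_cds <- list(
      alpha = make_pheromone_gene(spacer, seed = child_seed(seed, 3L), gc = config$mat_gc),
      a = make_pheromone_gene(spacer, seed = child_seed(seed, 4L), gc = config$mat_gc))

    gi <- function(role) which(genes$role == role)
    anc_gene <- setNames(vector("list", nrow(genes)), genes$name)
    for (i in seq_len(nrow(genes))) {
      anc_gene[[i]] <- switch(genes$role[i],
        MF = NA_character_,            # planted per class, not evolved
        HD = NA_character_,            # two distinct genes, below
        random_cds(genes$length[i], config$mat_gc))
    }
    sxi_anc <- list(SXI1 = random_cds(genes$length[gi("HD")], config$mat_gc),
                    SXI2 = random_cds(genes$length[gi("HD")], config$mat_gc))
    gap_seqs <- map_chr(layout$gaps, ~ random_nt(.x, config$mat_gc))
    flank_up <- random_nt(config$flank_len, config$background_gc)
    flank_down <- random_nt(layout$contig_len - layout$core_end,
                            config$background_gc)

    # --- assemble the ancestral core region and per-site masks ----------
    # minus-strand genes are stored reverse-complemented so that the
    # forward-strand region carries every CDS in its annotated orientation
    n <- nrow(genes)
    region_parts <- character(2L * n - 1L)
    for (i in seq_len(n)) {
      region_parts[2L * i - 1L] <- switch(genes$role[i],
        MF = strrep("A", mf_len), HD = strrep("A", genes$length[i]),
        if (genes$strand[i] == "-") revcomp(anc_gene[[i]]) else anc_gene[[i]])
      if (i < n) region_parts[2L * i] <- gap_seqs[i]
    }
    region_anc <- paste(region_parts, collapse = "")

    region_len <- nchar(region_anc)
    pos0 <- layout$core_start  # region sequence is contig[core_start, core_end)
    stopifnot(region_len == layout$core_end - layout$core_start)

    # per-site extra-divergence scale over the region (class-split pass)
    site_scale <- rep(1, region_len)
    if (config$homogenize_interior) {
      for (sg in segs) {
        lo <- sg$lo - pos0 + config$edge_zone
        hi <- sg$hi - pos0 - config$edge_zone
        if (hi > lo) site_scale[(lo + 1L):hi] <- config$interior_factor
      }
    }
    # mechanism mask: sites handled by dedicated passes are excluded from
    # the generic class-split pass
    special <- rep(FALSE, region_len)
    span_of <- function(i) (genes$start[i] - pos0 + 1L):(genes$end[i] - pos0)
    special[span_of(gi("MF"))] <- TRUE
    special[span_of(gi("STE3"))] <- TRUE
    special[span_of(gi("HD"))] <- TRUE

    # --- evolution passes ------------------------------------------------
    extra <- config$mat_suppression_extra
    classes_present <- unique(ste3_type_of(strains$class))
    extra_by_class <- setNames(as.list(rep(extra / 2, 2)), c("alpha", "a"))

    generic_idx <- which(!special)
    generic_anc <- paste(seq_chars(region_anc)[generic_idx], collapse = "")
    # positions of the generic genes inside the subsetted generic vector
    newpos <- cumsum(!special)
    generic_genes <- which(!(genes$role %in% c("MF", "STE3", "HD")))
    gmap <- make_cds_map(
      starts = newpos[genes$start[generic_genes] - pos0 + 1L] - 1L,
      ends = newpos[genes$end[generic_genes] - pos0],
      strands = genes$strand[generic_genes])
    generic_tips <- evolve_class_split(
      generic_anc, strain_tree, config$mat_gc, config$kappa,
      extra_by_class, site_scale = site_scale[generic_idx], cds_map = gmap)

    one_gene_map <- function(len) make_cds_map(0L, len, "+")
    ste3_depth_branch <- max(config$ste3_allele_depth -
      (config$tree_height + config$within_species_depth), 0)
    ste3_len <- genes$length[gi("STE3")]
    ste3_tips <- evolve_class_split(
      anc_gene[[gi("STE3")]], strain_tree, config$mat_gc, config$kappa,
      setNames(as.list(rep(ste3_depth_branch, 2)), c("alpha", "a")),
      cds_map = one_gene_map(ste3_len))

    hd_len <- genes$length[gi("HD")]
    sxi_tips <- list(
      SXI1 = evolve_part(sxi_anc$SXI1, strain_tree, config$mat_gc,
                         config$kappa, cds_map = one_gene_map(hd_len)),
      SXI2 = evolve_part(sxi_anc$SXI2, strain_tree, config$mat_gc,
                         config$kappa, cds_map = one_gene_map(hd_len)))

    flank_tips <- list(
      up = evolve_part(flank_up, strain_tree, config$background_gc, config$kappa),
      down = evolve_part(flank_down, strain_tree, config$background_gc, config$kappa))

    # --- background contigs ----------------------------------------------
    bg <- simulate_background(config, strain_tree)

    # --- per-strain assembly ---------------------------------------------
    assemblies <- list(); annotations <- list()
    for (si in seq_len(nrow(strains))) {
      st <- strains$strain_id[si]
      cl <- strains$class[si]
      mt <- ste3_type_of(cl)
      hd <- hd_gene_of(cl)

      region_chars <- seq_chars(strrep("N", region_len))
      region_chars[generic_idx] <- seq_chars(generic_tips[[mt]][[st]])
      insert_gene <- function(chars, i, cds) {
        if (genes$strand[i] == "-") cds <- revcomp(cds)
        chars[span_of(i)] <- seq_chars(cds)
        chars
      }
      region_chars <- insert_gene(region_chars, gi("STE3"), ste3_tips[[mt]][[st]])
      region_chars <- insert_gene(region_chars, gi("HD"), sxi_tips[[hd]][[st]])
      region_chars <- insert_gene(region_chars, gi("MF"), mf_cds[[mt]])
      region_str <- paste(region_chars, collapse = "")

      strain_genes <- mutate(genes,
        name = ifelse(.data$role == "HD", hd, .data$name),
        role = ifelse(.data$role == "HD", hd, .data$role))

      if (inverted_order(cl)) {
        for (sg in segs) {
          lo <- sg$lo - pos0; hi <- sg$hi - pos0  # region coords, half-open
          seg_str <- substring(region_str, lo + 1L, hi)
          region_str <- paste0(substring(region_str, 1L, lo), revcomp(seg_str),
                               substring(region_str, hi + 1L))
          inside <- strain_genes$start >= sg$lo & strain_genes$end <= sg$hi
          mi <- t(vapply(which(inside), function(i) {
            mirror_interval(strain_genes$start[i], strain_genes$end[i], sg$lo, sg$hi)
          }, numeric(2)))
          strain_genes$start[inside] <- as.integer(mi[, 1L])
          strain_genes$end[inside] <- as.integer(mi[, 2L])
          strain_genes$strand[inside] <-
            c("+" = "-", "-" = "+")[strain_genes$strand[inside]]
        }
      }

      mat_seq <- paste0(flank_tips$up[[st]], region_str, flank_tips$down[[st]])
      contigs <- seq_set(
        id = c("scaffold_mat", bg$contig_ids),
        seq = c(mat_seq, map_chr(bg$contig_ids, ~ bg$seqs[[.x]][[st]])),
        desc = rep("", 1L + length(bg$contig_ids)), alphabet = "nt")

      ann <- bind_rows(
        mutate(strain_genes,
               gene_id = sprintf("%s.%s", st, .data$name), contig = "scaffold_mat"),
        mutate(bg$genes, gene_id = sprintf("%s.%s", st, .data$name)))
      ann <- new_annotation(
        tibble(gene_id = ann$gene_id, contig = ann$contig,
               start = as.integer(ann$start), end = as.integer(ann$end),
               strand = ann$strand,
               cds_starts = map(ann$start, ~ as.integer(.x)),
               cds_ends = map(ann$end, ~ as.integer(.x)),
               coding_complete = TRUE, role = ann$role,
               product = ann$role),
        genome_id = st)
      assemblies[[st]] <- contigs
      annotations[[st]] <- ann
    }
  })

  truth <- list(
    config = config,
    strains = strains,
    species_tree = if (!is.null(species_tree)) write_newick(species_tree) else NA_character_,
    strain_tree = write_newick(strain_tree),
    mat_contig = "scaffold_mat",
    core_span = c(layout$core_start, layout$core_end),
    mf_span = c(genes$start[gi("MF")], genes$end[gi("MF")]),
    ste3_span = c(genes$start[gi("STE3")], genes$end[gi("STE3")]),
    hd_span = c(genes$start[gi("HD")], genes$end[gi("HD")]),
    pr_hd_gap = genes$start[gi("HD")] - genes$end[gi("STE3")],
    mf_spacer = spacer,
    inversion_segments = segs,
    breakpoint_intervals = map(segs, ~ list(left = .x$bp_left, right = .x$bp_right)),
    layout = genes,
    seed = seed)
  structure(list(assemblies = assemblies, annotations = annotations,
                 truth = truth), class = "mat_sim")
}

simulate_background <- function(config, strain_tree) {
  ncontig <- config$n_background_contigs
  if (ncontig == 0L) {
    return(list(contig_ids = character(), seqs = list(),
                genes = tibble(name = character(), role = character(),
                               length = integer(), strand = character(),
                               start = integer(), end = integer(),
                               contig = character(), orig_index = integer())))
  }
  contig_ids <- sprintf("scaffold_bg%d", seq_len(ncontig))
  seqs <- list(); gene_rows <- list()
  k <- 0L
  for (j in seq_len(ncontig)) {
    glen <- config$background_gene_len
    ngene <- config$background_genes_per_contig
    clen <- config$background_contig_len
    slack <- clen - ngene * glen
    gap <- slack %/% (ngene + 1L)
    parts <- character(); kinds <- character()
    pos <- 0L; starts <- integer(ngene); ends <- integer(ngene)
    for (g in seq_len(ngene)) {
      parts <- c(parts, random_nt(gap, config$background_gc))
      pos <- pos + gap
      starts[g] <- pos
      parts <- c(parts, random_cds(glen, config$background_gc))
      pos <- pos + glen
      ends[g] <- pos
    }
    parts <- c(parts, random_nt(clen - pos, config$background_gc))
    anc <- paste(parts, collapse = "")
    bg_map <- make_cds_map(starts, ends, rep("+", ngene))
    seqs[[contig_ids[j]]] <- evolve_part(anc, strain_tree,
                                         config$background_gc, config$kappa,
                                         cds_map = bg_map)
    gene_rows[[j]] <- tibble(
      name = sprintf("bg%d_%d", j, seq_len(ngene)), role = "other",
      length = glen, strand = "+", start = starts, end = ends,
      contig = contig_ids[j], orig_index = NA_integer_)
    k <- k + ngene
  }
  list(contig_ids = contig_ids, seqs = seqs, genes = bind_rows(gene_rows))
}

#' Extract the predicted proteome of a strain
#'
#' @param annotation A gene-model tibble.
#' @param assembly The matching nucleotide [seq_set()].
#' @return An amino-acid [seq_set()] keyed by gene_id.
#' @export
strain_proteome <- function(annotation, assembly) {
  ann <- annotation[annotation$coding_complete, ]
  single_exon <- map_int(ann$cds_starts, length) == 1L
  cds <- character(nrow(ann))
  # fast path: single-exon genes extracted and translated in batch
  if (any(single_exon)) {
    idx <- which(single_exon)
    contig_seq <- assembly$seq[match(ann$contig[idx], assembly$id)]
    cds[idx] <- substring(contig_seq, ann$start[idx] + 1L, ann$end[idx])
    minus <- idx[ann$strand[idx] == "-"]
    if (length(minus) > 0L) {
      cds[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(cds[minus])))
    }
  }
  for (i in which(!single_exon)) cds[i] <- gene_cds(ann[i, ], assembly)
  prot <- sub("\\*$", "", as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(cds),
                          if.fuzzy.codon = "solve"))))
  seq_set(id = ann$gene_id, seq = unname(prot), desc = ann$role %||% "",
          alphabet = "aa")
}

#' Write a simulated dataset to disk
#'
#' Emits one FASTA and one GFF3 per strain plus a machine-readable truth
#' record (JSON) and a seed manifest.
#'
#' @param sim A `mat_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(sim$assemblies)) {
    write_fasta(sim$assemblies[[st]], file.path(dir, paste0(st, ".fa")))
    write_gff3(sim$annotations[[st]], file.path(dir, paste0(st, ".gff3")))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- sim$truth
    tr$config$template <- NULL
    tr$layout <- as.data.frame(tr$layout[, c("name", "role", "length", "strand",
                                             "start", "end")])
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    writeLines(as.character(sim$truth$seed), file.path(dir, "seed.txt"))
  }
  invisible(dir)
}
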