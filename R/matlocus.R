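#' Classify a MAT allele from its STE3 type and HD gene
#'
#' The four reachable combinations follow the standard naming convention for
#' fused Trichosporonales MAT alleles: the A1/A2 designation is keyed to the
#' STE3 variant, with the SXI gene determining the starred variant.
#'
#' @param ste3_type `"a"`, `"alpha"` or `"unresolved"`.
#' @param hd_role `"SXI1"`, `"SXI2"` or `NA`.
#' @return One of `"A1"`, `"A2"`, `"A1*"`, `"A2*"`, `"unresolved"`.
#' @export
classify_allele <- function(ste3_type, hd_role) {
  if (is.na(ste3_type) || is.na(hd_role) ||
      !(ste3_type %in% c("a", "alpha")) || !(hd_role %in% c("SXI1", "SXI2"))) {
    return("unresolved")
  }
  key <- paste(ste3_type, hd_role, sep = "+")
  c("alpha+SXI2" = "A1", "a+SXI1" = "A2",
    "alpha+SXI1" = "A1*", "a+SXI2" = "A2*")[[key]]
}

COMPANION_ROLES <- c("STE11", "STE20", "IKS1", "MYO2", "RPL22", "STE12")

#' Locate and describe the fused MAT locus of a haploid genome
#'
#' Decides whether the HD (SXI) and P/R (STE3 + pheromone) loci are
#' physically linked, delimits the core MAT region (from the pheromone/STE3
#' end to the HD gene), and classifies the allele when an STE3 type is
#' supplied. Two HD genes on distinct contigs (a hybrid-like assembly) yield
#' one report per candidate subgenome, flagged `hybrid`.
#'
#' @param annotation A gene-model tibble (see [read_gff3()]).
#' @param roles A role assignment tibble from [assign_roles()] (columns
#'   `role`, `gene_id`), or `NULL` if `annotation$role` is already filled.
#' @param ste3_type Optional STE3 allele type (`"a"`/`"alpha"`) used for
#'   allele classification.
#' @param flank Distance (bp) around the core span within which companion
#'   genes are still counted.
#' @return A tibble with one row per report: `genome_id`, `status`
#'   (`ok`/`incomplete`/`hybrid`), `reason`, `contig`, `hd_gene`, `hd_role`,
#'   `ste3_gene`, `mf_gene`, `linked`, `distance_bp`, `core_start`,
#'   `core_end`, `allele`, `companions` (list-column of roles).
#' @export
locate_mat <- function(annotation, roles = NULL, ste3_type = NULL,
                       flank = 20000L) {
  ann <- annotation
  if (!is.null(roles)) {
    assigned <- roles[!is.na(roles$gene_id), c("role", "gene_id")]
    ann$role <- assigned$role[match(ann$gene_id, assigned$gene_id)]
  }
  genome_id <- attr(annotation, "genome_id") %||% NA_character_
  hd <- ann[!is.na(ann$role) & ann$role %in% c("SXI1", "SXI2"), ]
  ste3 <- ann[!is.na(ann$role) & ann$role == "STE3", ]
  mf <- ann[!is.na(ann$role) & ann$role == "MF", ]

  incomplete <- function(reason) {
    tibble(genome_id = genome_id, status = "incomplete", reason = reason,
           contig = NA_character_, hd_gene = NA_character_,
           hd_role = NA_character_, ste3_gene = NA_character_,
           mf_gene = NA_character_, linked = NA, distance_bp = NA_integer_,
           core_start = NA_integer_, core_end = NA_integer_,
           allele = "unresolved", companions = list(character()))
  }
  if (nrow(hd) == 0L) return(incomplete("HD locus not found"))
  if (nrow(ste3) == 0L) return(incomplete("P/R locus not found"))

  hybrid <- nrow(hd) > 1L && length(unique(hd$contig)) > 1L
  reports <- map(seq_len(nrow(hd)), function(i) {
    one_mat_report(ann, hd[i, ], ste3, mf, genome_id, ste3_type, flank,
                   status = if (hybrid) "hybrid" else "ok")
  })
  out <- bind_rows(reports)
  if (!hybrid && nrow(out) > 1L) out <- out[1L, ]
  out
}

one_mat_report <- function(ann, hd, ste3_all, mf_all, genome_id, ste3_type,
                           flank, status) {
  # prefer the P/R genes on the HD contig; fall back to the global best
  ste3 <- ste3_all[ste3_all$contig == hd$contig, ]
  if (nrow(ste3) == 0L) ste3 <- ste3_all
  ste3 <- ste3[1L, ]
  linked <- identical(ste3$contig, hd$contig)
  distance <- if (linked) {
    max(max(ste3$start, hd$start) - min(ste3$end, hd$end), 0L)
  } else NA_integer_
  mf <- mf_all[mf_all$contig == hd$contig | mf_all$contig == ste3$contig, ]
  core <- if (linked) {
    span_genes <- bind_rows(ste3, hd, if (nrow(mf)) mf[1L, ])
    c(min(span_genes$start), max(span_genes$end))
  } else c(NA_integer_, NA_integer_)
  companions <- if (linked) {
    inside <- ann$contig == hd$contig &
      ann$end > core[1L] - flank & ann$start < core[2L] + flank &
      !is.na(ann$role) & ann$role %in% COMPANION_ROLES
    sort(unique(ann$role[inside]))
  } else character()
  allele <- if (!is.null(ste3_type)) classify_allele(ste3_type, hd$role) else
    "unresolved"
  tibble(genome_id = genome_id, status = status, reason = NA_character_,
         contig = hd$contig, hd_gene = hd$gene_id, hd_role = hd$role,
         ste3_gene = ste3$gene_id,
         mf_gene = if (nrow(mf)) mf$gene_id[1L] else NA_character_,
         linked = linked, distance_bp = as.integer(distance),
         core_start = as.integer(core[1L]), core_end = as.integer(core[2L]),
         allele = allele, companions = list(companions))
}
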