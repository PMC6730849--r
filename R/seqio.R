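#' Sequence sets as tibbles
#'
#' A sequence set is a tibble with columns `id`, `seq` and `desc`, one row per
#' record, carrying an `alphabet` attribute (`"nt"` or `"aa"`). Sequences are
#' uppercase; IUPAC ambiguity codes are preserved.
#'
#' @param id,seq,desc Character vectors of equal length.
#' @param alphabet `"nt"`, `"aa"`, or `NULL` to guess from the residues.
#' @return A `seq_set` tibble.
#' @export
seq_set <- function(id = character(), seq = character(),
                    desc = rep("", length(id)), alphabet = NULL) {
  seq <- toupper(seq)
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate sequence id '%s'", id[duplicated(id)][1L]))
  }
  alphabet <- alphabet %||% guess_alphabet(seq)
  validate_alphabet(seq, id, alphabet)
  out <- tibble(id = as.character(id), seq = seq, desc = as.character(desc))
  attr(out, "alphabet") <- alphabet
  class(out) <- c("seq_set", class(out))
  out
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("# A seq_set: %d %s record(s)\n", nrow(x),
              attr(x, "alphabet") %||% "?"))
  NextMethod()
}

#' Parse FASTA text into a sequence set
#'
#' @param text FASTA content as a single string or character vector of lines.
#' @param alphabet `"nt"`, `"aa"`, or `NULL` to guess.
#' @return A [seq_set()] tibble; record order follows the input.
#' @export
parse_fasta <- function(text, alphabet = NULL) {
  path <- tempfile(fileext = ".fa")
  on.exit(unlink(path), add = TRUE)
  writeLines(paste(text, collapse = "\n"), path)
  read_fasta(path, alphabet = alphabet)
}

#' Read a FASTA file into a sequence set
#'
#' @param path Path to a FASTA file.
#' @inheritParams parse_fasta
#' @return A [seq_set()] tibble.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (length(readLines(path, n = 1L)) == 0L) return(seq_set(alphabet = alphabet))
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_set(id = id, seq = unname(as.character(ss)), desc = desc,
          alphabet = alphabet)
}

#' Write a sequence set to FASTA
#'
#' @param x A [seq_set()] tibble (or any tibble with `id`, `seq`, `desc`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(desc[[i]])) paste(x$id[[i]], desc[[i]]) else x$id[[i]]
    writeLines(paste0(">", hdr), con)
    s <- x$seq[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

new_annotation <- function(genes, genome_id = NA_character_) {
  genes <- arrange(genes, .data$contig, .data$start, .data$gene_id)
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicate gene_id '%s'",
                  genes$gene_id[duplicated(genes$gene_id)][1L]))
  }
  attr(genes, "genome_id") <- genome_id
  class(genes) <- c("mat_annotation", setdiff(class(genes), "mat_annotation"))
  genes
}

empty_annotation <- function(genome_id = NA_character_) {
  new_annotation(tibble(
    gene_id = character(), contig = character(),
    start = integer(), end = integer(), strand = character(),
    cds_starts = list(), cds_ends = list(),
    coding_complete = logical(), role = character(), product = character()),
    genome_id)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`CDS` features into a gene-model tibble. External
#' GFF3 coordinates are 1-based inclusive; internally every interval is
#' half-open and 0-based on the forward strand, so a GFF3 feature at
#' `101..200` becomes `start = 100, end = 200`. CDS parts are grouped under
#' their gene via `Parent` links; a `##FASTA` directive terminates feature
#' parsing. Genes whose total CDS length is not divisible by 3 are flagged
#' `coding_complete = FALSE` rather than rejected.
#'
#' @param path Path to a GFF3 file.
#' @param assembly Optional [seq_set()]; if given, CDS features referencing a
#'   contig absent from the assembly are an error.
#' @param genome_id Optional label stored on the result.
#' @return A `mat_annotation` tibble with columns `gene_id`, `contig`,
#'   `start`, `end`, `strand`, `cds_starts`, `cds_ends` (0-based half-open
#'   list-columns), `coding_complete`, `role`, `product`, sorted by
#'   (contig, start).
#' @export
read_gff3 <- function(path, assembly = NULL, genome_id = NA_character_) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  check_gff3_lines(readLines(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gff3_to_annotation(gr, assembly = assembly, genome_id = genome_id)
}

#' Parse GFF3 text into gene models
#'
#' @param text GFF3 content as a single string or character vector of lines.
#' @inheritParams read_gff3
#' @return See [read_gff3()].
#' @export
parse_gff3 <- function(text, assembly = NULL, genome_id = NA_character_) {
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path), add = TRUE)
  writeLines(paste(text, collapse = "\n"), path)
  read_gff3(path, assembly = assembly, genome_id = genome_id)
}

# Pre-scan for malformed coordinates so errors carry line numbers.
check_gff3_lines <- function(lines) {
  fasta_at <- which(startsWith(lines, "##FASTA"))
  feat_end <- if (length(fasta_at)) fasta_at[1L] - 1L else length(lines)
  for (i in seq_len(feat_end)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) next
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (!is.na(s) && !is.na(e) && e < s) {
      abort(sprintf("GFF3 line %d: end (%d) < start (%d)", i, e, s))
    }
  }
  invisible(TRUE)
}

gff3_to_annotation <- function(gr, assembly = NULL, genome_id = NA_character_) {
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID %||% rep(NA_character_, length(gr)))
  parents <- md$Parent
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))

  is_gene <- type == "gene"
  is_mrna <- type == "mRNA"
  is_cds <- type == "CDS"
  mrna_to_gene <- setNames(parent1[is_mrna], ids[is_mrna])

  if (!is.null(assembly) && any(is_cds)) {
    unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(gr[is_cds]))),
                       assembly$id)
    if (length(unknown) > 0L) {
      abort(sprintf("CDS references unknown contig '%s'", unknown[[1L]]))
    }
  }

  gene_idx <- which(is_gene)
  genes <- map(gene_idx, function(i) {
    gid <- ids[[i]]
    # CDS whose Parent is the gene itself or one of its mRNAs
    own_mrnas <- names(mrna_to_gene)[mrna_to_gene == gid]
    cds_i <- which(is_cds & (parent1 %in% c(gid, own_mrnas)))
    cs <- sort(GenomicRanges::start(gr)[cds_i]) - 1L
    ce <- sort(GenomicRanges::end(gr)[cds_i])
    prod <- md$product
    tibble(
      gene_id = gid,
      contig = as.character(GenomicRanges::seqnames(gr))[i],
      start = GenomicRanges::start(gr)[i] - 1L,
      end = GenomicRanges::end(gr)[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      cds_starts = list(as.integer(cs)), cds_ends = list(as.integer(ce)),
      coding_complete = length(cds_i) > 0L && sum(ce - cs) %% 3L == 0L,
      role = NA_character_,
      product = if (!is.null(prod) && !is.na(prod[i])) as.character(prod[i]) else "")
  })
  new_annotation(bind_rows(genes) %||% empty_annotation(), genome_id)
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/CDS lines, converting internal 0-based half-open
#' coordinates back to GFF3's 1-based inclusive convention. Output is
#' byte-stable for a given annotation.
#'
#' @param annotation A `mat_annotation` tibble (see [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("##gff-version 3", con)
  ann <- arrange(annotation, .data$contig, .data$start, .data$gene_id)
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    s1 <- g$start + 1L
    attrs <- sprintf("ID=%s", g$gene_id)
    if (!is.na(g$role)) attrs <- paste0(attrs, ";role=", g$role)
    if (nzchar(g$product %||% "")) attrs <- paste0(attrs, ";product=", g$product)
    writeLines(sprintf("%s\tmatloci\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       g$contig, s1, g$end, g$strand, attrs), con)
    writeLines(sprintf("%s\tmatloci\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.m1;Parent=%s",
                       g$contig, s1, g$end, g$strand, g$gene_id, g$gene_id), con)
    cs <- g$cds_starts[[1]]; ce <- g$cds_ends[[1]]
    for (k in seq_along(cs)) {
      writeLines(sprintf("%s\tmatloci\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.m1",
                         g$contig, cs[k] + 1L, ce[k], g$strand, g$gene_id, k,
                         g$gene_id), con)
    }
  }
  invisible(path)
}

#' Convert features to BED intervals
#'
#' BED is 0-based half-open, matching the internal convention, so
#' `BED start = GFF3 start - 1` and `BED end = GFF3 end`.
#'
#' @param x A tibble with `contig`, `start`, `end` and optionally
#'   `gene_id`/`name` and `strand` columns (internal 0-based coordinates).
#' @return A tibble with BED columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
as_bed <- function(x) {
  nm <- x$gene_id %||% x$name %||% rep(".", nrow(x))
  tibble(chrom = x$contig, start = as.integer(x$start), end = as.integer(x$end),
         name = nm, score = rep(0L, nrow(x)),
         strand = x$strand %||% rep(".", nrow(x)))
}

#' Write a BED table
#' @param bed A tibble from [as_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the spliced CDS of a gene, strand-aware
#'
#' @param gene One row of a `mat_annotation`.
#' @param assembly A nucleotide [seq_set()].
#' @return The CDS string in translation orientation.
#' @export
gene_cds <- function(gene, assembly) {
  contig_seq <- assembly$seq[match(gene$contig, assembly$id)]
  if (is.na(contig_seq)) abort(sprintf("contig '%s' not in assembly", gene$contig))
  cs <- gene$cds_starts[[1]]; ce <- gene$cds_ends[[1]]
  parts <- substring(contig_seq, cs + 1L, ce)
  cds <- paste(parts, collapse = "")
  if (identical(gene$strand, "-")) revcomp(cds) else cds
}
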