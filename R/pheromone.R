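#' Enumerate open reading frames on both strands
#'
#' Every ORF runs from an ATG to the first in-frame stop codon, on either
#' strand, under the standard genetic code. Reverse-strand ORFs are reported
#' in forward-strand coordinates (0-based half-open). ORFs containing IUPAC
#' ambiguity codes are skipped.
#'
#' @param contig A nucleotide string.
#' @param min_aa,max_aa Peptide-length bounds (stop excluded).
#' @param contig_id Label for the output.
#' @return A tibble with columns `contig`, `start`, `end`, `strand`,
#'   `peptide`; `end - start == 3 * (nchar(peptide) + 1)`.
#' @export
enumerate_orfs <- function(contig, min_aa = 20L, max_aa = 65L,
                           contig_id = "contig") {
  if (min_aa > max_aa) abort("min_aa must be <= max_aa")
  fwd <- orfs_one_strand(toupper(contig), min_aa, max_aa)
  rc <- orfs_one_strand(revcomp(contig), min_aa, max_aa)
  n <- nchar(contig)
  out <- bind_rows(
    if (nrow(fwd)) mutate(fwd, strand = "+"),
    if (nrow(rc)) mutate(rc, strand = "-",
                         start2 = n - .data$end, end = n - .data$start,
                         start = .data$start2, start2 = NULL))
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), peptide = character()))
  }
  out |>
    mutate(contig = contig_id) |>
    select("contig", "start", "end", "strand", "peptide") |>
    arrange(.data$start, .data$strand)
}

# ORFs on one strand of `x`, coordinates 0-based half-open on that strand.
# Codons carrying ambiguity codes terminate the scan for the ORFs that reach
# them (such ORFs are skipped rather than expanded).
orfs_one_strand <- function(x, min_aa, max_aa) {
  n <- nchar(x)
  code <- codon_info()$code
  empty <- tibble(start = integer(), end = integer(), peptide = character())
  if (n < 6L) return(empty)
  out <- list()
  for (f in 0:2) {
    s <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(s) == 0L) next
    codons <- substring(x, s, s + 2L)
    aa <- unname(code[codons])
    is_stop <- !is.na(aa) & aa == "*"
    event <- which(is_stop | is.na(aa))  # stop or ambiguous codon
    atg <- which(codons == "ATG")
    if (length(atg) == 0L || length(event) == 0L) next
    pos <- findInterval(atg, event) + 1L
    nxt <- ifelse(pos <= length(event), event[pos], NA_integer_)
    keep <- !is.na(nxt) & is_stop[nxt]
    atg <- atg[keep]; nxt <- nxt[keep]
    len <- nxt - atg  # peptide length in residues
    sel <- len >= min_aa & len <= max_aa
    atg <- atg[sel]; nxt <- nxt[sel]
    if (length(atg) == 0L) next
    pep <- vapply(seq_along(atg), function(i) {
      paste(aa[atg[i]:(nxt[i] - 1L)], collapse = "")
    }, character(1))
    out[[length(out) + 1L]] <-
      tibble(start = s[atg] - 1L, end = s[nxt] + 2L, peptide = pep)
  }
  bind_rows(out) %||% empty
}

#' Match a peptide against the pheromone-precursor consensus
#'
#' The consensus is `M-X(15-60)-C-[ILMVST]-[ILMVST]-X-Stop`: an initiator
#' methionine, an unconstrained spacer of 15 to 60 residues, then a
#' C-terminal CaaX box whose cysteine sits four residues from the end, the
#' two following residues drawn from I/L/M/V/S/T and the final residue free
#' (the stop codon terminates the ORF immediately after it).
#'
#' @param peptide An amino-acid string without internal stops.
#' @return A list with `match` (logical), `spacer_len` and `caax` (the
#'   terminal 4 residues), the latter two `NA` on no-match.
#' @export
match_pheromone_consensus <- function(peptide) {
  no <- list(match = FALSE, spacer_len = NA_integer_, caax = NA_character_)
  L <- nchar(peptide)
  if (L < 20L || L > 65L) return(no)
  if (substr(peptide, 1L, 1L) != "M") return(no)
  if (substr(peptide, L - 3L, L - 3L) != "C") return(no)
  aliph <- c("I", "L", "M", "V", "S", "T")
  if (!(substr(peptide, L - 2L, L - 2L) %in% aliph)) return(no)
  if (!(substr(peptide, L - 1L, L - 1L) %in% aliph)) return(no)
  list(match = TRUE, spacer_len = L - 5L, caax = substr(peptide, L - 3L, L))
}

#' Scan an assembly for pheromone-precursor candidates
#'
#' Enumerates ORFs with peptide lengths in `[min_spacer + 5, max_spacer + 5]`
#' on both strands of every contig and keeps those matching the consensus
#' (see [match_pheromone_consensus()]).
#'
#' @param assembly A nucleotide [seq_set()].
#' @param min_spacer,max_spacer Spacer-length bounds (residues).
#' @return A tibble of hits sorted by (contig, start): `contig`, `start`,
#'   `end`, `strand`, `peptide`, `spacer_len`, `caax`.
#' @export
scan_pheromones <- function(assembly, min_spacer = 15L, max_spacer = 60L) {
  hits <- map(seq_len(nrow(assembly)), function(i) {
    orfs <- enumerate_orfs(assembly$seq[[i]], min_aa = min_spacer + 5L,
                           max_aa = max_spacer + 5L,
                           contig_id = assembly$id[[i]])
    if (nrow(orfs) == 0L) return(NULL)
    m <- map(orfs$peptide, match_pheromone_consensus)
    keep <- map_lgl(m, "match")
    orfs <- orfs[keep, ]
    orfs$spacer_len <- map_int(m[keep], "spacer_len")
    orfs$caax <- map_chr(m[keep], "caax")
    sl <- orfs$spacer_len
    orfs[sl >= min_spacer & sl <= max_spacer, ]
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), peptide = character(),
                  spacer_len = integer(), caax = character()))
  }
  arrange(out, .data$contig, .data$start, .data$strand)
}

#' Write pheromone hits as GFF3 and optionally BED
#'
#' @param hits A tibble from [scan_pheromones()].
#' @param gff3_path Output GFF3 path.
#' @param bed_path Optional BED path.
#' @param fasta_path Optional peptide FASTA sidecar.
#' @return `gff3_path`, invisibly.
#' @export
write_pheromone_hits <- function(hits, gff3_path, bed_path = NULL,
                                 fasta_path = NULL) {
  con <- file(gff3_path, "wt"); on.exit(close(con), add = TRUE)
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "%s\tmatloci\tpheromone_precursor\t%d\t%d\t.\t%s\t0\tID=pher%d;spacer=%d;caax=%s",
      hits$contig[i], hits$start[i] + 1L, hits$end[i], hits$strand[i], i,
      hits$spacer_len[i], hits$caax[i]), con)
  }
  if (!is.null(bed_path)) {
    write_bed(as_bed(mutate(hits, gene_id = sprintf("pher%d", row_number()))),
              bed_path)
  }
  if (!is.null(fasta_path)) {
    write_fasta(seq_set(id = sprintf("pher%d", seq_len(nrow(hits))),
                        seq = hits$peptide, alphabet = "aa"), fasta_path)
  }
  invisible(gff3_path)
}
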