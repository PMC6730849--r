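#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap
#' @importFrom stringr str_sub str_length str_count str_detect str_split
#' @importFrom stats setNames
#' @useDynLib matloci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC alphabets; sequences are stored uppercase, ambiguity codes preserved.
IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-", ".")
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*", "-", ".")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Split a sequence into a character vector of single residues
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string (IUPAC-aware)
#'
#' @param x A single nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate an in-frame CDS to protein using the standard genetic code
#'
#' The terminal stop codon, if present, is trimmed from the returned peptide.
#'
#' @param cds A nucleotide string whose length is divisible by 3.
#' @return A single amino-acid string without the terminal stop.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) %% 3 != 0) {
    abort(sprintf("CDS length %d is not divisible by 3", nchar(cds)))
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "solve"))
  sub("\\*$", "", aa)
}

guess_alphabet <- function(seqs) {
  if (length(seqs) == 0L) return("nt")
  chars <- unique(seq_chars(paste(substr(seqs, 1L, 200L), collapse = "")))
  if (all(chars %in% IUPAC_NT)) "nt" else "aa"
}

validate_alphabet <- function(seqs, ids, alphabet) {
  allowed <- if (alphabet == "nt") IUPAC_NT else AA_CODES
  for (i in seq_along(seqs)) {
    bad <- which(!(seq_chars(seqs[[i]]) %in% allowed))
    if (length(bad) > 0L) {
      abort(sprintf(
        "record '%s': character '%s' at position %d is not a valid IUPAC %s code",
        ids[[i]], substr(seqs[[i]], bad[1L], bad[1L]), bad[1L],
        if (alphabet == "nt") "nucleotide" else "amino-acid"))
    }
  }
  invisible(TRUE)
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

#' Derive a stream of child seeds from a master seed
#'
#' Deterministic and collision-unlikely for the handful of streams a pipeline
#' uses; keeps every value below 2^31.
#' @noRd
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629
}
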