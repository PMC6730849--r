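# Standard genetic code (translation table 1), shared by the ORF scanner,
# the simulator's codon samplers, RSCU and the NG86 machinery.

.matloci <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

codon_info <- function() {
  if (!is.null(.matloci$codon_info)) return(.matloci$codon_info)
  code <- genetic_code()
  info <- list(
    code = code,
    codons = names(code),
    sense = names(code)[code != "*"],
    stops = names(code)[code == "*"])
  info$aa <- code[info$sense]
  .matloci$codon_info <- info
  info
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate codons to amino acids ("*" for stops, NA for ambiguous codons)
#' @noRd
codons_to_aa <- function(codons) {
  code <- codon_info()$code
  unname(code[codons])
}

# Equilibrium base frequencies at a given GC fraction, order A,C,G,T.
base_freqs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

# Probability weight of each codon under independent equilibrium base draws.
codon_weights <- function(codons, gc) {
  pi <- base_freqs(gc)
  m <- matrix(match(unlist(strsplit(codons, "")), c("A", "C", "G", "T")),
              ncol = 3L, byrow = TRUE)
  pi[m[, 1L]] * pi[m[, 2L]] * pi[m[, 3L]]
}

# Sample a random coding sequence: ATG start, sense codons, one stop codon.
# `len` includes the stop codon and must be divisible by 3.
random_cds <- function(len, gc) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ci <- codon_info()
  n_mid <- len / 3L - 2L
  mid <- sample(ci$sense, n_mid, replace = TRUE, prob = codon_weights(ci$sense, gc))
  stop_codon <- sample(ci$stops, 1L, prob = codon_weights(ci$stops, gc))
  paste(c("ATG", mid, stop_codon), collapse = "")
}

# Random non-coding sequence at equilibrium GC.
random_nt <- function(len, gc) {
  if (len == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = base_freqs(gc)),
        collapse = "")
}

# Reverse-translate a peptide, choosing synonymous codons with probability
# proportional to their equilibrium weight at `gc`.
reverse_translate <- function(peptide, gc) {
  ci <- codon_info()
  vapply(seq_chars(peptide), function(a) {
    cands <- ci$sense[ci$aa == a]
    if (length(cands) == 0L) abort(sprintf("no codon for residue '%s'", a))
    if (length(cands) == 1L) return(cands)
    sample(cands, 1L, prob = codon_weights(cands, gc))
  }, character(1), USE.NAMES = FALSE)
}
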