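#' GC-content window track
#'
#' Non-overlapping windows tiled from the sequence start; each value is the
#' percentage (G+C)/(A+C+G+T) with ambiguity codes excluded from both
#' numerator and denominator. The trailing partial window is emitted with a
#' flag. The coverage-weighted mean of window values equals the
#' whole-sequence GC exactly.
#'
#' @param seq A nucleotide string.
#' @param window Window size in bp (default 2000).
#' @return A `window_track` tibble: `start`, `end`, `value` (GC percent,
#'   `NA` if a window has no unambiguous base), `partial`.
#' @export
gc_windows <- function(seq, window = 2000L) {
  if (window < 1L) abort("window must be >= 1")
  empty <- tibble(start = integer(), end = integer(), value = numeric(),
                  partial = logical())
  if (!nzchar(seq)) {
    attr(empty, "window_size") <- as.integer(window)
    class(empty) <- c("window_track", class(empty))
    return(empty)
  }
  seq <- toupper(seq)
  n <- nchar(seq)
  starts <- seq(1L, n, by = window)
  ends <- pmin(starts + window - 1L, n)
  frags <- substring(seq, starts, ends)
  gc <- str_count(frags, "[GC]")
  at <- str_count(frags, "[AT]")
  denom <- gc + at
  out <- tibble(start = starts - 1L, end = ends,
                value = ifelse(denom > 0, 100 * gc / denom, NA_real_),
                partial = (ends - starts + 1L) < window)
  attr(out, "window_size") <- as.integer(window)
  class(out) <- c("window_track", class(out))
  out
}

#' GC percentage of a nucleotide string (ambiguity codes excluded)
#' @param seq A nucleotide string (or vector, concatenated).
#' @return GC percent.
#' @export
gc_percent <- function(seq) {
  s <- toupper(paste(seq, collapse = ""))
  gc <- str_count(s, "[GC]"); at <- str_count(s, "[AT]")
  if (gc + at == 0) return(NA_real_)
  100 * gc / (gc + at)
}

#' Per-CDS GC content
#'
#' GC percent of each gene's spliced CDS (strand-independent, GC being
#' complement-invariant), with the genome-wide GC reported as an attribute.
#'
#' @param annotation A gene-model tibble.
#' @param assembly The matching nucleotide [seq_set()].
#' @return A tibble `gene_id`, `contig`, `role`, `gc`; attribute
#'   `genome_gc` holds the whole-assembly GC percent.
#' @export
cds_gc <- function(annotation, assembly) {
  rows <- map(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    cds <- gene_cds(g, assembly)
    if (!nzchar(cds)) {
      warn(sprintf("gene '%s' has a zero-length CDS; skipped", g$gene_id))
      return(NULL)
    }
    tibble(gene_id = g$gene_id, contig = g$contig,
           role = g$role %||% NA_character_, gc = gc_percent(cds))
  })
  out <- bind_rows(rows)
  attr(out, "genome_gc") <- gc_percent(assembly$seq)
  out
}

#' Relative synonymous codon usage (RSCU)
#'
#' Codon counts pooled over a set of in-frame coding sequences; each sense
#' codon's RSCU is its count divided by the mean count of its synonymous
#' family. Families never observed are absent from the output; single-codon
#' families (Met, Trp) have RSCU 1 by convention when observed.
#'
#' @param cds_set A character vector or [seq_set()] of in-frame CDS
#'   (terminal stop codons are trimmed; internal stops are an error).
#' @return A tibble: `codon`, `aa`, `family_size`, `count`, `rscu`.
#' @export
rscu <- function(cds_set) {
  seqs <- if (is.data.frame(cds_set)) cds_set$seq else cds_set
  ci <- codon_info()
  counts <- setNames(numeric(length(ci$sense)), ci$sense)
  for (s in seqs) {
    if (nchar(s) %% 3 != 0) abort("CDS length not divisible by 3")
    codons <- split_codons(toupper(s))
    aa <- codons_to_aa(codons)
    n <- length(codons)
    if (!is.na(aa[n]) && aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
    if (any(!is.na(aa) & aa == "*")) abort("internal stop codon in CDS")
    keep <- codons %in% ci$sense
    tab <- table(codons[keep])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  fam <- tibble(codon = ci$sense, aa = unname(ci$aa), count = unname(counts)) |>
    group_by(.data$aa) |>
    mutate(family_size = n(), family_total = sum(.data$count)) |>
    ungroup() |>
    filter(.data$family_total > 0) |>
    mutate(rscu = .data$count * .data$family_size / .data$family_total) |>
    select("codon", "aa", "family_size", "count", "rscu") |>
    arrange(.data$aa, .data$codon)
  fam
}

#' Mann-Whitney rank-sum test with an exact small-sample null
#'
#' One-sided Mann-Whitney U test using midranks for ties. When
#' `n1 * n2 <= 400` the p-value comes from the exact permutation null of the
#' rank sum (computed by dynamic programming over the observed midranks, so
#' ties are handled exactly); otherwise a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x,y Numeric samples (the alternative is about `x` relative to `y`).
#' @param alternative `"less"` (x tends smaller) or `"greater"`.
#' @return A `ranksum_result` list: `U`, `n1`, `n2`, `p_value`, `method`
#'   (`exact`/`normal-approximation`/`degenerate`), `alternative`,
#'   `degenerate` flag.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort("each sample needs at least 2 values")
  comb <- c(x, y)
  r <- rank(comb)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (length(unique(comb)) == 1L) {
    return(structure(list(U = U, n1 = n1, n2 = n2, p_value = 1,
                          method = "degenerate", alternative = alternative,
                          degenerate = TRUE), class = "ranksum_result"))
  }
  if (n1 * n2 <= 400L) {
    p <- ranksum_exact_p(r, n1, W, alternative)
    method <- "exact"
  } else {
    p <- ranksum_normal_p(r, n1, n2, U, alternative)
    method <- "normal-approximation"
  }
  structure(list(U = U, n1 = n1, n2 = n2, p_value = p, method = method,
                 alternative = alternative, degenerate = FALSE),
            class = "ranksum_result")
}

# Exact permutation distribution of the doubled rank sum via a
# generating-function DP over subsets of size n1.
ranksum_exact_p <- function(r, n1, W, alternative) {
  w <- as.integer(round(2 * r))
  N <- length(w)
  S <- sum(w)
  # f[k+1, s+1] = number of k-subsets with doubled rank sum s
  f <- matrix(0, n1 + 1L, S + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(N)) {
    kmax <- min(i, n1)
    for (k in kmax:1L) {
      wi <- w[i]
      f[k + 1L, (wi + 1L):(S + 1L)] <-
        f[k + 1L, (wi + 1L):(S + 1L)] + f[k, 1L:(S + 1L - wi)]
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  W2 <- as.integer(round(2 * W))
  if (alternative == "less") {
    sum(counts[seq_len(W2 + 1L)]) / total
  } else {
    sum(counts[(W2 + 1L):(S + 1L)]) / total
  }
}

ranksum_normal_p <- function(r, n1, n2, U, alternative) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(sigma2)
  if (alternative == "less") {
    stats::pnorm((U - mu + 0.5) / sigma)
  } else {
    1 - stats::pnorm((U - mu - 0.5) / sigma)
  }
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s, alternative '%s'): U = %.1f (n1=%d, n2=%d), p = %.4g\n",
              x$method, x$alternative, x$U, x$n1, x$n2, x$p_value))
  invisible(x)
}
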