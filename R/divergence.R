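#' Nei-Gojobori (1986) synonymous/nonsynonymous counts for a codon pair
#'
#' Site fractions: at each codon position the fraction of the three one-step
#' changes that are synonymous (changes producing stop codons count as
#' nonsynonymous). Difference counts: the synonymous/nonsynonymous labels of
#' the mutational steps, averaged over all orderings of the differing
#' positions; orderings passing through stop codons are excluded (if every
#' ordering is blocked, all are included with stop-crossing steps counted
#' nonsynonymous).
#'
#' @param codon_a,codon_b Sense codons (3-letter A/C/G/T strings).
#' @return A list: `s_a`, `s_b` (synonymous site fractions of each codon),
#'   `Sd`, `Nd` (averaged difference counts; `Sd + Nd` equals the number of
#'   differing positions).
#' @export
ng86_counts <- function(codon_a, codon_b) {
  code <- codon_info()$code
  for (cod in c(codon_a, codon_b)) {
    if (is.na(code[cod]) || code[cod] == "*") {
      abort(sprintf("'%s' is not a sense codon", cod))
    }
  }
  d <- ng86_pair_diff(codon_a, codon_b)
  list(s_a = ng86_syn_sites(codon_a), s_b = ng86_syn_sites(codon_b),
       Sd = d[[1L]], Nd = d[[2L]])
}

ng86_syn_sites <- function(codon) {
  code <- codon_info()$code
  aa <- code[codon]
  chars <- seq_chars(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(NT4, chars[pos])) {
      alt <- chars; alt[pos] <- b
      alt_aa <- code[paste(alt, collapse = "")]
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  unname(s)
}

ORDERINGS <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

ng86_pair_diff <- function(codon_a, codon_b) {
  code <- codon_info()$code
  ca <- seq_chars(codon_a); cb <- seq_chars(codon_b)
  diff_pos <- which(ca != cb)
  d <- length(diff_pos)
  if (d == 0L) return(c(0, 0))
  walk <- function(ordering) {
    cur <- ca
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (pos in diff_pos[ordering]) {
      nxt <- cur; nxt[pos] <- cb[pos]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*" && !identical(nxt, cb)) blocked <- TRUE
      if (aa1 != "*" && aa2 != "*" && aa1 == aa2) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn, blocked)
  }
  paths <- map(ORDERINGS[[as.character(d)]], walk)
  open <- map_lgl(paths, ~ .x[3L] == 0)
  use <- if (any(open)) paths[open] else paths
  m <- do.call(rbind, use)
  c(mean(m[, 1L]), mean(m[, 2L]))
}

# Cached per-pair tables over the 61 sense codons: synonymous site fractions
# (vector) and averaged Sd/Nd difference counts (61 x 61 matrices).
ng86_tables <- function() {
  if (!is.null(.matloci$ng86)) return(.matloci$ng86)
  sense <- codon_info()$sense
  n <- length(sense)
  s <- vapply(sense, ng86_syn_sites, numeric(1))
  Sd <- matrix(0, n, n, dimnames = list(sense, sense))
  Nd <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (j < i) { Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]; next }
      d <- ng86_pair_diff(sense[i], sense[j])
      Sd[i, j] <- d[1L]; Nd[i, j] <- d[2L]
    }
  }
  .matloci$ng86 <- list(sense = sense, s = s, Sd = Sd, Nd = Nd)
  .matloci$ng86
}

#' Protein-guided codon alignment of two coding sequences
#'
#' The translated proteins are globally aligned and the alignment is
#' back-translated onto codons. Codon pairs containing a gap or an ambiguity
#' code are dropped and counted.
#'
#' @param cds_a,cds_b In-frame coding sequences (length divisible by 3; the
#'   terminal stop codon, if present, is trimmed; internal stops are an
#'   error).
#' @param scheme Protein [scoring_scheme()].
#' @param name_a,name_b Names used in error messages.
#' @return A `codon_alignment` list: `pairs` (tibble `codon_a`, `codon_b`),
#'   `n_codons`, `n_dropped_gap`.
#' @export
codon_align <- function(cds_a, cds_b, scheme = scoring_scheme("aa"),
                        name_a = "cds_a", name_b = "cds_b") {
  prep <- function(cds, nm) {
    if (nchar(cds) %% 3 != 0) {
      abort(sprintf("%s: length %d not divisible by 3", nm, nchar(cds)))
    }
    codons <- split_codons(toupper(cds))
    aa <- codons_to_aa(codons)
    n <- length(codons)
    if (!is.na(aa[n]) && aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
    if (any(!is.na(aa) & aa == "*")) {
      abort(sprintf("%s contains an internal stop codon", nm))
    }
    list(codons = codons, aa = aa)
  }
  a <- prep(cds_a, name_a); b <- prep(cds_b, name_b)
  pep <- function(p) paste(ifelse(is.na(p$aa), "X", p$aa), collapse = "")
  aln <- align_global(pep(a), pep(b), scheme)
  ga <- seq_chars(aln$aligned_a); gb <- seq_chars(aln$aligned_b)
  ia <- 0L; ib <- 0L
  pa <- character(0); pb <- character(0); dropped <- 0L
  for (k in seq_along(ga)) {
    if (ga[k] != "-") ia <- ia + 1L
    if (gb[k] != "-") ib <- ib + 1L
    if (ga[k] == "-" || gb[k] == "-") { dropped <- dropped + 1L; next }
    codon_a <- a$codons[ia]; codon_b <- b$codons[ib]
    if (grepl("[^ACGT]", codon_a) || grepl("[^ACGT]", codon_b)) {
      dropped <- dropped + 1L; next
    }
    pa <- c(pa, codon_a); pb <- c(pb, codon_b)
  }
  structure(list(pairs = tibble(codon_a = pa, codon_b = pb),
                 n_codons = length(pa), n_dropped_gap = dropped),
            class = "codon_alignment")
}

#' Estimate dS and dN from a codon alignment (NG86 + Jukes-Cantor)
#'
#' Synonymous site totals are the mean of the two sequences' per-codon sums;
#' difference counts are summed over codon pairs; proportions are corrected
#' with the Jukes-Cantor formula `d = -(3/4) log(1 - (4/3) p)`. Estimates
#' are `undefined` when the logarithm argument is non-positive (printed as
#' "Un" in output tables). Standard errors come from a seeded codon-
#' resampling bootstrap; the SE is reported as `NA` when more than 10% of
#' replicates are undefined.
#'
#' @param aln A [codon_align()] result.
#' @param bootstrap_B Bootstrap replicates (0 skips the SE).
#' @param seed Integer seed for the bootstrap.
#' @param min_codons Minimum aligned codons (error below this floor).
#' @return A tibble row: `n_codons`, `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `SE_dS`, `SE_dN`, `status` (`ok`/`undefined`).
#' @export
estimate_ds <- function(aln, bootstrap_B = 1000L, seed = 1L, min_codons = 10L) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons < min_codons) {
    abort(sprintf("only %d aligned codons (floor %d)", aln$n_codons, min_codons))
  }
  tab <- ng86_tables()
  ia <- match(aln$pairs$codon_a, tab$sense)
  ib <- match(aln$pairs$codon_b, tab$sense)
  if (anyNA(ia) || anyNA(ib)) abort("alignment contains stop codons")
  sa <- tab$s[ia]; sb <- tab$s[ib]
  sd_v <- tab$Sd[cbind(ia, ib)]; nd_v <- tab$Nd[cbind(ia, ib)]
  n <- aln$n_codons

  jc <- function(p) {
    arg <- 1 - (4 / 3) * p
    if (arg <= 0) NA_real_ else -(3 / 4) * log(arg)
  }
  summarize_counts <- function(sel) {
    S_sites <- (sum(sa[sel]) + sum(sb[sel])) / 2
    N_sites <- 3 * length(sel) - S_sites
    Sd <- sum(sd_v[sel]); Nd <- sum(nd_v[sel])
    pS <- if (S_sites > 0) Sd / S_sites else NA_real_
    pN <- if (N_sites > 0) Nd / N_sites else NA_real_
    c(S_sites, N_sites, Sd, Nd, pS, pN, jc(pS), jc(pN))
  }
  full <- summarize_counts(seq_len(n))
  SE_dS <- NA_real_; SE_dN <- NA_real_
  if (bootstrap_B > 0L) {
    reps <- with_seed(seed, {
      vapply(seq_len(bootstrap_B), function(b) {
        r <- summarize_counts(sample.int(n, n, replace = TRUE))
        c(r[7L], r[8L])
      }, numeric(2))
    })
    if (mean(is.na(reps[1L, ])) <= 0.10) SE_dS <- stats::sd(reps[1L, ], na.rm = TRUE)
    if (mean(is.na(reps[2L, ])) <= 0.10) SE_dN <- stats::sd(reps[2L, ], na.rm = TRUE)
  }
  tibble(n_codons = n, S_sites = full[1L], N_sites = full[2L],
         Sd = full[3L], Nd = full[4L], pS = full[5L], pN = full[6L],
         dS = full[7L], dN = full[8L], SE_dS = SE_dS, SE_dN = SE_dN,
         status = if (is.na(full[7L])) "undefined" else "ok")
}

#' Closest-pair similarity calls for a gene with three alleles
#'
#' For each gene present in three strains, the three pairwise local
#' nucleotide alignment scores are compared and the most similar pair is
#' called, labelled by the strains' allele classes (e.g. `A2/A2` vs
#' `A1/A2`). Exact score ties are `ambiguous`; genes missing an allele are
#' `not_assessed`.
#'
#' @param allele_tbl A tibble with columns `gene`, `strain`, `cds`.
#' @param labels Named character vector: strain -> allele class.
#' @param scheme Nucleotide [scoring_scheme()].
#' @return A tibble: `gene`, `status`, `most_similar_pair` (strain ids),
#'   `pair_classes`, `margin`.
#' @export
closest_pair_calls <- function(allele_tbl, labels, scheme = scoring_scheme("nt")) {
  out <- allele_tbl |>
    group_by(.data$gene) |>
    group_map(function(g, key) {
      if (nrow(g) < 3L) {
        return(tibble(gene = key$gene, status = "not_assessed",
                      most_similar_pair = NA_character_,
                      pair_classes = NA_character_, margin = NA_real_))
      }
      g <- g[1:3, ]
      pairs <- utils::combn(3L, 2L)
      scores <- apply(pairs, 2L, function(p) {
        local_score(g$cds[p[1L]], g$cds[p[2L]], scheme)
      })
      best <- which.max(scores)
      tie <- sum(scores == scores[best]) > 1L
      lab <- function(k) {
        p <- pairs[, k]
        paste(sort(g$strain[p]), collapse = "|")
      }
      cls <- function(k) {
        p <- pairs[, k]
        paste(sort(unname(labels[g$strain[p]])), collapse = "/")
      }
      tibble(gene = key$gene,
             status = if (tie) "ambiguous" else "called",
             most_similar_pair = if (tie) NA_character_ else lab(best),
             pair_classes = if (tie) NA_character_ else cls(best),
             margin = scores[best] - max(scores[-best]))
    }) |>
    bind_rows()
  arrange(out, .data$gene)
}

#' One-sided Student's t-test comparing two sets of per-gene dS values
#'
#' Pooled-variance two-sample t-test of the alternative that the
#' between-mating-type dS values exceed the within-mating-type values.
#' Undefined dS entries must be removed beforehand (NAs are dropped here).
#'
#' @param ds_between,ds_within Numeric vectors of per-gene dS.
#' @return A `matloci_ttest` object with `statistic`, `df`, `p_value`,
#'   `n1`, `n2`, `mean_between`, `mean_within`; see [generics::tidy()].
#' @export
compare_ds_sets <- function(ds_between, ds_within) {
  x <- ds_between[!is.na(ds_between)]
  y <- ds_within[!is.na(ds_within)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each dS set needs at least 2 defined values")
  }
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 <= 0) {
    t_stat <- if (isTRUE(all.equal(mean(x), mean(y)))) 0 else
      sign(mean(x) - mean(y)) * Inf
    p <- if (t_stat == 0) 0.5 else if (t_stat > 0) 0 else 1
  } else {
    ht <- stats::t.test(x, y, var.equal = TRUE, alternative = "greater")
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(list(statistic = t_stat, df = df, p_value = p, n1 = n1, n2 = n2,
                 mean_between = mean(x), mean_within = mean(y)),
            class = "matloci_ttest")
}

#' @export
print.matloci_ttest <- function(x, ...) {
  cat(sprintf(
    "One-sided pooled t-test (between > within dS)\n  t = %.4f, df = %d, p = %.4g\n  mean between = %.4g (n=%d), mean within = %.4g (n=%d)\n",
    x$statistic, x$df, x$p_value, x$mean_between, x$n1, x$mean_within, x$n2))
  invisible(x)
}

#' Breakpoint-versus-interior similarity test (suspension-bridge pattern)
#'
#' Windows of a similarity track are classed as `breakpoint` (overlapping a
#' detected breakpoint interval, extended by `flank_windows` windows on each
#' side) or `interior` (inside an inverted block and not breakpoint-classed);
#' a one-sided rank-sum test asks whether breakpoint similarity is lower.
#' Track and blocks must share the query (A) coordinate system.
#'
#' @param track A [window_similarity()] track.
#' @param blocks A [detect_blocks()] result.
#' @param flank_windows Windows added on each side of a breakpoint overlap.
#' @return A `ranksum_result` (see [rank_sum_test()]) with attributes
#'   `n_breakpoint` and `n_interior`.
#' @export
breakpoint_divergence_test <- function(track, blocks, flank_windows = 2L) {
  tr <- track[!track$partial, ]
  nw <- nrow(tr)
  bp_idx <- rep(FALSE, nw)
  for (k in seq_len(nrow(blocks$breakpoints))) {
    lo <- blocks$breakpoints$a_lo[k]; hi <- blocks$breakpoints$a_hi[k]
    hit <- which(tr$end > lo & tr$start < hi)
    if (length(hit) > 0L) {
      lo_i <- max(1L, min(hit) - flank_windows)
      hi_i <- min(nw, max(hit) + flank_windows)
      bp_idx[lo_i:hi_i] <- TRUE
    }
  }
  inv <- blocks$blocks[blocks$blocks$orientation == "inverted", ]
  interior_idx <- rep(FALSE, nw)
  for (k in seq_len(nrow(inv))) {
    mid <- (tr$start + tr$end) / 2
    interior_idx[mid >= inv$a_start[k] & mid <= inv$a_end[k]] <- TRUE
  }
  interior_idx <- interior_idx & !bp_idx
  if (sum(bp_idx) < 3L || sum(interior_idx) < 3L) {
    abort(sprintf("insufficient windows (breakpoint %d, interior %d)",
                  sum(bp_idx), sum(interior_idx)))
  }
  res <- rank_sum_test(tr$value[bp_idx], tr$value[interior_idx],
                       alternative = "less")
  attr(res, "n_breakpoint") <- sum(bp_idx)
  attr(res, "n_interior") <- sum(interior_idx)
  res
}
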