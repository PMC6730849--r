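#' Alignment scoring schemes
#'
#' BLAST-like defaults: BLOSUM62 with gap open 11 / extend 1 for proteins,
#' match +2 / mismatch -3 with gap open 5 / extend 2 for nucleotides. Gap
#' penalties are stored as positive numbers and applied negatively; opening
#' a gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param alphabet `"aa"` or `"nt"`.
#' @param match,mismatch Nucleotide scores (ignored for `"aa"`).
#' @param matrix Protein substitution matrix name (ignored for `"nt"`).
#' @param gap_open,gap_extend Affine gap penalties (non-negative).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(alphabet = c("aa", "nt"), match = 2, mismatch = -3,
                           matrix = "BLOSUM62", gap_open = NULL,
                           gap_extend = NULL) {
  alphabet <- match.arg(alphabet)
  gap_open <- gap_open %||% if (alphabet == "aa") 11 else 5
  gap_extend <- gap_extend %||% if (alphabet == "aa") 1 else 2
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be >= 0")
  structure(list(alphabet = alphabet, match = match, mismatch = mismatch,
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

subst_matrix <- function(scheme) {
  if (scheme$alphabet == "aa") {
    key <- paste0("submat_", scheme$matrix)
    if (is.null(.matloci[[key]])) {
      e <- new.env()
      utils::data(list = scheme$matrix, package = "Biostrings", envir = e)
      .matloci[[key]] <- get(scheme$matrix, envir = e)
    }
    .matloci[[key]]
  } else {
    Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                             mismatch = scheme$mismatch,
                                             baseOnly = FALSE)
  }
}

as_xstring <- function(x, scheme) {
  if (scheme$alphabet == "aa") Biostrings::AAString(x) else Biostrings::DNAString(x)
}

# Guard against passing one protein and one nucleotide sequence. Nucleotide
# strings are valid amino-acid strings, so this is necessarily heuristic:
# flag only when one side carries residues that cannot be nucleotides while
# the other is a non-trivial pure A/C/G/T/U string.
check_same_alphabet <- function(a, b) {
  definite_aa <- function(x) grepl("[EFILOPQXZJ*]", x)
  pure_nt <- function(x) nchar(x) >= 6 && !grepl("[^ACGTU]", x)
  if ((definite_aa(a) && pure_nt(b)) || (definite_aa(b) && pure_nt(a))) {
    abort("mixed alphabets: inputs do not share a residue alphabet")
  }
}

alignment_result <- function(pa) {
  a <- as.character(Biostrings::alignedPattern(pa))
  b <- as.character(Biostrings::alignedSubject(pa))
  ca <- seq_chars(a); cb <- seq_chars(b)
  ident <- if (nchar(a) == 0L) 0 else mean(ca == cb & ca != "-")
  structure(list(score = Biostrings::score(pa), identity = ident,
                 aligned_a = a, aligned_b = b), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: score %.1f, identity %.3f, length %d>\n",
              x$score, x$identity, nchar(x$aligned_a)))
  invisible(x)
}

#' Optimal global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' @param a,b Residue strings of a common alphabet.
#' @param scheme A [scoring_scheme()]; defaults to the protein scheme.
#' @return An `alignment_result`: `score`, `identity` (fraction of alignment
#'   columns with identical residues), `aligned_a`, `aligned_b`.
#' @export
align_global <- function(a, b, scheme = scoring_scheme("aa")) {
  if (!nzchar(a) || !nzchar(b)) {
    n <- max(nchar(a), nchar(b))
    score <- if (n == 0) 0 else -(scheme$gap_open + scheme$gap_extend * n)
    return(structure(list(
      score = score, identity = 0,
      aligned_a = if (nzchar(a)) a else strrep("-", n),
      aligned_b = if (nzchar(b)) b else strrep("-", n)),
      class = "alignment_result"))
  }
  check_same_alphabet(a, b)
  pa <- Biostrings::pairwiseAlignment(
    as_xstring(toupper(a), scheme), as_xstring(toupper(b), scheme),
    type = "global", substitutionMatrix = subst_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  alignment_result(pa)
}

#' Optimal local nucleotide alignment (Smith-Waterman, affine gaps)
#'
#' @param a,b Nucleotide strings.
#' @param scheme A nucleotide [scoring_scheme()].
#' @return An `alignment_result`; score is 0 when no positive-scoring
#'   segment exists.
#' @export
align_local_nt <- function(a, b, scheme = scoring_scheme("nt")) {
  stopifnot(scheme$alphabet == "nt")
  if (!nzchar(a) || !nzchar(b)) {
    return(structure(list(score = 0, identity = 0, aligned_a = "",
                          aligned_b = ""), class = "alignment_result"))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "local", substitutionMatrix = subst_matrix(scheme),
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  res <- alignment_result(pa)
  if (res$score < 0) {
    res$score <- 0; res$identity <- 0; res$aligned_a <- ""; res$aligned_b <- ""
  }
  res
}

# Score matrix between two sequence sets (rows = queries, cols = targets),
# scores only -- used for reciprocal-best-hit searches. Runs through the
# compiled Gotoh engine (same conventions as pairwiseAlignment; the
# equivalence is asserted in the test suite).
align_score_matrix <- function(queries, targets, scheme = scoring_scheme("aa")) {
  m <- score_matrix_cpp(toupper(queries$seq), toupper(targets$seq),
                        subst_matrix(scheme), scheme$gap_open,
                        scheme$gap_extend, FALSE)
  dimnames(m) <- list(queries$id, targets$id)
  m
}

# Local-alignment score only (Smith-Waterman, floored at 0).
local_score <- function(a, b, scheme = scoring_scheme("nt")) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  max(score_matrix_cpp(toupper(a), toupper(b), subst_matrix(scheme),
                       scheme$gap_open, scheme$gap_extend, TRUE)[1L, 1L], 0)
}

#' Assign MAT roles to proteins by reciprocal best hit against a panel
#'
#' Each panel entry is labelled with a MAT role. For every role the
#' best-scoring query under global alignment is found; the role is assigned
#' only if that query's best panel hit (over all entries) carries the same
#' role (reciprocal best hit on score). Ties between queries are flagged and
#' broken by lexicographic gene id. Pairs scoring below `min_score` or with
#' identity below `min_identity` are left unassigned.
#'
#' @param proteome An amino-acid [seq_set()] of query proteins.
#' @param panel An amino-acid [seq_set()] with a `role` column.
#' @param scheme Protein [scoring_scheme()].
#' @param min_score,min_identity Assignment floor.
#' @return A tibble with one row per panel role: `role`, `gene_id` (NA when
#'   unassigned), `score`, `second_best_score`, `identity`, `flag`
#'   (`unique`/`tie`/`one_way`), `assigned`.
#' @export
assign_roles <- function(proteome, panel, scheme = scoring_scheme("aa"),
                         min_score = 50, min_identity = 0.25) {
  if (nrow(panel) == 0L) abort("reference panel is empty")
  if (!("role" %in% names(panel))) abort("panel must carry a 'role' column")
  if (nrow(proteome) == 0L) abort("proteome is empty")
  S <- align_score_matrix(proteome, panel, scheme)
  roles <- unique(panel$role)
  # each query's best panel entry decides the query's preferred role
  q_best_role <- panel$role[max.col(S, ties.method = "first")]
  out <- map(roles, function(rl) {
    cols <- which(panel$role == rl)
    sub <- S[, cols, drop = FALSE]
    best_per_query <- apply(sub, 1L, max)
    ord <- order(-best_per_query, proteome$id)
    top <- ord[1L]
    tie <- sum(best_per_query == best_per_query[top]) > 1L
    second <- if (length(ord) > 1L) best_per_query[ord[2L]] else NA_real_
    flag <- if (tie) "tie" else "unique"
    qid <- proteome$id[top]
    reciprocal <- q_best_role[top] == rl
    if (!reciprocal) flag <- "one_way"
    ident <- align_global(proteome$seq[top],
                          panel$seq[cols[which.max(sub[top, ])]],
                          scheme)$identity
    assigned <- reciprocal && best_per_query[top] >= min_score &&
      ident >= min_identity
    tibble(role = rl, gene_id = if (assigned) qid else NA_character_,
           score = best_per_query[top], second_best_score = second,
           identity = ident, flag = flag, assigned = assigned)
  })
  bind_rows(out)
}

#' Type an STE3 pheromone receptor as the a or alpha allele class
#'
#' The query is globally aligned to every reference; the class of the
#' best-scoring reference wins unless the margin over the other class falls
#' below `margin_frac` of the best score, in which case the call is
#' `unresolved`. When the call is alpha, the presence of the alpha-group
#' conserved N-terminal proline at the reference-anchored column is reported
#' as an advisory flag (it never overrides the similarity call).
#'
#' @param ste3_protein Query amino-acid string.
#' @param refs An amino-acid [seq_set()] with a `class` column of values
#'   `"a"`/`"alpha"`.
#' @param scheme Protein [scoring_scheme()].
#' @param margin_frac Unresolved margin, as a fraction of the best score.
#' @return A tibble row: `type` (`a`/`alpha`/`unresolved`), `best_score`,
#'   `margin`, `alpha_proline` (logical, NA unless type is alpha).
#' @export
type_ste3 <- function(ste3_protein, refs, scheme = scoring_scheme("aa"),
                      margin_frac = 0.05) {
  if (!("class" %in% names(refs))) abort("refs must carry a 'class' column")
  for (cl in c("a", "alpha")) {
    if (!any(refs$class == cl)) abort(sprintf("no '%s' reference provided", cl))
  }
  scores <- vapply(refs$seq, function(r) {
    Biostrings::pairwiseAlignment(
      as_xstring(toupper(ste3_protein), scheme), as_xstring(toupper(r), scheme),
      type = "global", substitutionMatrix = subst_matrix(scheme),
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  best_by_class <- vapply(c("a", "alpha"),
                          function(cl) max(scores[refs$class == cl]), numeric(1))
  best <- max(best_by_class)
  margin <- abs(diff(best_by_class))
  type <- if (margin < margin_frac * abs(best)) "unresolved" else
    names(best_by_class)[which.max(best_by_class)]
  alpha_pro <- NA
  if (identical(type, "alpha")) {
    ref_i <- which(refs$class == "alpha")[which.max(scores[refs$class == "alpha"])]
    aln <- align_global(ste3_protein, refs$seq[ref_i], scheme)
    rb <- seq_chars(aln$aligned_b); ra <- seq_chars(aln$aligned_a)
    ref_pos <- cumsum(rb != "-")
    pcol <- which(rb == "P" & ref_pos <= 40L)[1L]
    alpha_pro <- if (is.na(pcol)) NA else identical(ra[pcol], "P")
  }
  tibble(type = type, best_score = best, margin = margin,
         alpha_proline = alpha_pro)
}
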