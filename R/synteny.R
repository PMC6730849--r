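#' Map ortholog anchors between two annotated regions
#'
#' Orthologs are reciprocal best hits by global protein alignment score.
#' Each anchor records the two gene midpoints and whether the annotated
#' strands agree (`same`) or not (`flipped`).
#'
#' @param genes_a,genes_b Gene-model tibbles for the two regions.
#' @param proteins_a,proteins_b Amino-acid [seq_set()]s keyed by gene_id.
#' @param scheme Protein [scoring_scheme()].
#' @return A tibble sorted by `pos_a`: `gene_a`, `gene_b`, `pos_a`, `pos_b`,
#'   `strand_a`, `strand_b`, `rel_orientation`, `score`.
#' @export
anchor_map <- function(genes_a, proteins_a, genes_b, proteins_b,
                       scheme = scoring_scheme("aa")) {
  empty <- tibble(gene_a = character(), gene_b = character(),
                  pos_a = numeric(), pos_b = numeric(),
                  strand_a = character(), strand_b = character(),
                  rel_orientation = character(), score = numeric())
  pa <- proteins_a[proteins_a$id %in% genes_a$gene_id, ]
  pb <- proteins_b[proteins_b$id %in% genes_b$gene_id, ]
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(empty)
  S <- align_score_matrix(pa, pb, scheme)
  best_b_for_a <- max.col(S, ties.method = "first")
  best_a_for_b <- max.col(t(S), ties.method = "first")
  rows <- list()
  for (i in seq_len(nrow(pa))) {
    j <- best_b_for_a[i]
    if (best_a_for_b[j] != i) next
    ga <- genes_a[match(pa$id[i], genes_a$gene_id), ]
    gb <- genes_b[match(pb$id[j], genes_b$gene_id), ]
    rows[[length(rows) + 1L]] <- tibble(
      gene_a = ga$gene_id, gene_b = gb$gene_id,
      pos_a = (ga$start + ga$end) / 2, pos_b = (gb$start + gb$end) / 2,
      strand_a = ga$strand, strand_b = gb$strand,
      rel_orientation = if (ga$strand == gb$strand) "same" else "flipped",
      score = S[i, j])
  }
  out <- bind_rows(rows) %||% empty
  if (nrow(out)) arrange(out, .data$pos_a) else out
}

#' Partition ortholog anchors into colinear and inverted synteny blocks
#'
#' Greedy maximal runs of anchors with constant orientation and monotone
#' `pos_b` (increasing for colinear, decreasing for inverted), scanning in
#' `pos_a` order. Runs shorter than `min_anchors` are excluded from blocks
#' and reported as singletons. Breakpoints are the open intervals between
#' the outermost anchor positions of adjacent blocks, in A coordinates.
#'
#' @param anchors An anchor tibble from [anchor_map()], sorted by `pos_a`.
#' @param min_anchors Minimum anchors per reported block.
#' @return A `synteny_blocks` list: `blocks` (tibble with `block_id`,
#'   `orientation`, `n_anchors`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `genes` list-column), `breakpoints` (tibble `a_lo`, `a_hi`), and
#'   `singletons` (anchor tibble).
#' @export
detect_blocks <- function(anchors, min_anchors = 2L) {
  runs <- list()
  n <- nrow(anchors)
  i <- 1L
  while (i <= n) {
    ori <- anchors$rel_orientation[i]
    dir <- if (ori == "same") 1 else -1
    j <- i
    while (j + 1L <= n &&
           anchors$rel_orientation[j + 1L] == ori &&
           sign(anchors$pos_b[j + 1L] - anchors$pos_b[j]) == dir) {
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  is_block <- map_int(runs, length) >= min_anchors
  blocks <- imap(runs[is_block], function(idx, k) {
    sub <- anchors[idx, ]
    tibble(block_id = k,
           orientation = if (sub$rel_orientation[1L] == "same") "colinear" else "inverted",
           n_anchors = nrow(sub),
           a_start = min(sub$pos_a), a_end = max(sub$pos_a),
           b_start = min(sub$pos_b), b_end = max(sub$pos_b),
           genes = list(sub$gene_a))
  })
  blocks <- bind_rows(blocks) %||%
    tibble(block_id = integer(), orientation = character(),
           n_anchors = integer(), a_start = numeric(), a_end = numeric(),
           b_start = numeric(), b_end = numeric(), genes = list())
  breakpoints <- if (nrow(blocks) > 1L) {
    tibble(a_lo = blocks$a_end[-nrow(blocks)], a_hi = blocks$a_start[-1L])
  } else {
    tibble(a_lo = numeric(), a_hi = numeric())
  }
  singletons <- anchors[unlist(runs[!is_block]) %||% integer(), ]
  structure(list(blocks = blocks, breakpoints = breakpoints,
                 singletons = singletons, anchors = anchors),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks: %d block(s) (%d inverted), %d singleton(s), %d breakpoint interval(s)>\n",
              nrow(x$blocks), sum(x$blocks$orientation == "inverted"),
              nrow(x$singletons), nrow(x$breakpoints)))
  print(x$blocks, ...)
  invisible(x)
}

#' Sliding-fragment similarity track between two regions
#'
#' The query is tiled into non-overlapping fragments of `fragment` bp; each
#' fragment's value is its best local-alignment score against the target,
#' both strands searched (0 when no positive-scoring segment exists). This
#' mirrors BLASTN best-hit score profiles of 1-kb fragments.
#'
#' @param query,target Nucleotide strings.
#' @param fragment Fragment length in bp (>= 100).
#' @param scheme Nucleotide [scoring_scheme()].
#' @return A `window_track` tibble: `start`, `end`, `value`, `partial`
#'   (flagging the final short fragment), with a `window_size` attribute.
#' @export
window_similarity <- function(query, target, fragment = 1000L,
                              scheme = scoring_scheme("nt")) {
  if (fragment < 100L) abort("fragment length below 100 bp is degenerate")
  if (!nzchar(query) || !nzchar(target)) abort("both regions must be non-empty")
  n <- nchar(query)
  starts <- seq(1L, n, by = fragment)
  ends <- pmin(starts + fragment - 1L, n)
  frags <- substring(query, starts, ends)
  sm <- subst_matrix(scheme)
  score_vs <- function(subject) {
    pmax(score_matrix_cpp(toupper(frags), subject, sm, scheme$gap_open,
                          scheme$gap_extend, TRUE)[, 1L], 0)
  }
  vals <- pmax(score_vs(toupper(target)), score_vs(revcomp(target)))
  out <- tibble(start = starts - 1L, end = ends, value = vals,
                partial = (ends - starts + 1L) < fragment)
  attr(out, "window_size") <- as.integer(fragment)
  class(out) <- c("window_track", class(out))
  out
}
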