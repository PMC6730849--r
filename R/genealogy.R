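#' Pairwise distances from aligned sequences
#'
#' p-distance (mismatches over compared sites) or Jukes-Cantor corrected
#' distance for nucleotides; columns where either sequence carries a gap or
#' ambiguity code are deleted pairwise. JC entries are undefined (NA,
#' flagged) when p >= 3/4.
#'
#' @param seqs A named character vector or [seq_set()] of equal-length
#'   aligned sequences.
#' @param model `"p"` or `"JC"` (JC for nucleotides only).
#' @return A `dist_matrix` list: `labels`, `d` (symmetric matrix, NA where
#'   undefined), `model`, `undefined` (logical matrix).
#' @export
pairwise_distances <- function(seqs, model = c("p", "JC")) {
  model <- match.arg(model)
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (length(unique(nchar(seqs))) != 1L) {
    abort("sequences must be aligned to equal length")
  }
  alphabet <- guess_alphabet(unname(seqs))
  if (model == "JC" && alphabet != "nt") {
    abort("JC correction applies to nucleotide sequences only")
  }
  valid_set <- if (alphabet == "nt") NT4 else setdiff(AA_CODES, c("X", "*", "-", ".", "B", "Z"))
  M <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  ok <- matrix(M %in% valid_set, nrow = nrow(M))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  undef <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        d[i, j] <- d[j, i] <- NA_real_
        undef[i, j] <- undef[j, i] <- TRUE
        next
      }
      p <- mean(M[i, comp] != M[j, comp])
      val <- if (model == "p") p else {
        if (p >= 0.75) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * p)
      }
      if (is.na(val)) undef[i, j] <- undef[j, i] <- TRUE
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(list(labels = names(seqs), d = d, model = model,
                 undefined = undef), class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch so path lengths are
#' preserved through the parent node.
#'
#' @param D A [pairwise_distances()] result or a symmetric numeric matrix
#'   with dimnames.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "dist_matrix")) D$d else D
  if (nrow(d) < 3L) abort("at least 3 taxa are required")
  na_at <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(na_at) > 0L) {
    abort(sprintf("undefined distance between '%s' and '%s'",
                  rownames(d)[na_at[1L, 1L]], colnames(d)[na_at[1L, 2L]]))
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sib) > 0L) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

# All non-trivial bipartitions of an unrooted tree, as lists of tip labels
# (the side not containing the first tip is returned for each internal edge).
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", n_tip + tree$Nnode)
  for (t in seq_len(n_tip)) below[[t]] <- t
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1L]; chi <- po$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[chi]])
  }
  splits <- list()
  for (k in seq_len(nrow(po$edge))) {
    chi <- po$edge[k, 2L]
    if (chi <= n_tip) next  # trivial split
    side <- sort(below[[chi]])
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    splits[[length(splits) + 1L]] <- tree$tip.label[side]
  }
  splits
}

#' Classify a gene genealogy as mating-type or species clustering
#'
#' `mating_type` when some bipartition of the unrooted tree separates all
#' tips of one allele class from all tips of the other (the signature of
#' trans-species polymorphism); `species` when no such bipartition exists
#' and every species with two or more tips is separated from all other tips
#' by some bipartition; `mixed` otherwise. Invariant to rerooting and tip
#' order.
#'
#' @param tree An `ape::phylo` tree.
#' @param labels A tibble/data.frame with columns `tip`, `species`, `class`.
#' @return A list: `pattern` (`mating_type`/`species`/`mixed`),
#'   `supporting` (list of tip-label sets of the supporting bipartitions).
#' @export
classify_clustering <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% labels$tip)) {
    abort(sprintf("tip '%s' is not labelled", setdiff(tips, labels$tip)[1L]))
  }
  lab <- labels[match(tips, labels$tip), ]
  classes <- unique(lab$class)
  if (length(classes) != 2L) abort("exactly two allele classes are required")
  for (cl in classes) if (!any(lab$class == cl)) abort("empty allele class")
  species <- unique(lab$species)
  for (sp in species) if (!any(lab$species == sp)) abort("empty species")

  splits <- tree_splits(tree)
  matches_set <- function(set) {
    any(map_lgl(splits, function(s) {
      setequal(s, set) || setequal(s, setdiff(tips, set))
    }))
  }
  class_set <- tips[lab$class == classes[1L]]
  # with 2 tips of one class in a 4-tip tree the complement is the other class
  mt <- if (length(class_set) == 1L || length(class_set) == length(tips) - 1L) {
    FALSE  # trivial split cannot attest trans-specific clustering
  } else {
    matches_set(class_set)
  }
  if (mt) {
    return(list(pattern = "mating_type", supporting = list(sort(class_set))))
  }
  multi <- species[map_int(species, ~ sum(lab$species == .x)) >= 2L]
  sp_ok <- map_lgl(multi, function(sp) {
    set <- tips[lab$species == sp]
    if (length(set) >= length(tips) - 1L) TRUE else matches_set(set)
  })
  if (length(multi) > 0L && all(sp_ok)) {
    return(list(pattern = "species",
                supporting = map(multi, ~ sort(tips[lab$species == .x]))))
  }
  list(pattern = "mixed", supporting = list())
}
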