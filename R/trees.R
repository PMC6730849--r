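#' Serialize a tree to Newick
#'
#' @param tree An `ape::phylo` tree with labelled tips and non-negative
#'   branch lengths.
#' @param digits Significant digits for branch lengths (default 10, enough
#'   for lossless round-trips at the precision the pipeline uses).
#' @return A single Newick string terminated by `;`.
#' @export
write_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label))) {
    abort("all tips must be labelled")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("branch lengths must be non-negative")
  }
  ape::write.tree(tree, digits = digits)
}

#' Parse a Newick string
#'
#' @param text A Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) abort("could not parse Newick string")
  tr
}
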