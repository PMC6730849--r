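#' HKY-style nucleotide substitution model
#'
#' A reversible substitution model parameterized by its equilibrium GC
#' fraction (stationary frequencies are `(1-gc)/2` for A and T, `gc/2` for C
#' and G), a transition/transversion rate ratio `kappa`, and an overall rate
#' in expected substitutions per site per unit branch length. The rate matrix
#' is normalized so that branch lengths are in substitutions/site.
#'
#' @param gc Equilibrium GC fraction, in (0, 1).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param rate Rate multiplier applied to branch lengths (default 1).
#' @return An object of class `hky_model`.
#' @export
hky_model <- function(gc = 0.5, kappa = 2, rate = 1) {
  if (!(gc > 0 && gc < 1)) abort("gc must lie strictly between 0 and 1")
  if (kappa <= 0) abort("kappa must be positive")
  if (rate < 0) abort("rate must be non-negative")
  structure(list(gc = gc, kappa = kappa, rate = rate, pi = base_freqs(gc)),
            class = "hky_model")
}

# Normalized HKY rate matrix, base order A,C,G,T.
hky_rate_matrix <- function(model) {
  pi <- model$pi
  k <- model$kappa
  is_transition <- matrix(FALSE, 4, 4)
  is_transition[1, 3] <- is_transition[3, 1] <- TRUE  # A<->G
  is_transition[2, 4] <- is_transition[4, 2] <- TRUE  # C<->T
  Q <- matrix(rep(pi, each = 4), 4, 4)
  Q[is_transition] <- Q[is_transition] * k
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Transition probability matrix P(t) via symmetric eigen-decomposition.
hky_pmatrix <- function(model, t) {
  if (t <= 0) return(diag(4))
  Q <- hky_rate_matrix(model)
  sp <- sqrt(model$pi)
  S <- diag(sp) %*% Q %*% diag(1 / sp)  # symmetric for reversible Q
  e <- eigen(S, symmetric = TRUE)
  P <- diag(1 / sp) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

NT4 <- c("A", "C", "G", "T")

nt_to_idx <- function(seq) {
  idx <- match(seq_chars(seq), NT4)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    abort(sprintf("invalid nucleotide '%s' at position %d",
                  substr(seq, bad, bad), bad))
  }
  idx
}

idx_to_nt <- function(idx) paste(NT4[idx], collapse = "")

# Evolve state indices along one branch. `t` is a scalar branch length or a
# per-site vector (substitutions/site, already rate-scaled).
evolve_branch_idx <- function(idx, t, model) {
  out <- idx
  if (length(t) == 1L) {
    if (t <= 0) return(out)
    P <- hky_pmatrix(model, t)
    for (s in 1:4) {
      here <- which(idx == s)
      if (length(here) > 0L) {
        out[here] <- sample.int(4L, length(here), replace = TRUE, prob = P[s, ])
      }
    }
    return(out)
  }
  stopifnot(length(t) == length(idx))
  for (tu in unique(t)) {
    if (tu <= 0) next
    P <- hky_pmatrix(model, tu)
    sel <- which(t == tu)
    for (s in 1:4) {
      here <- sel[idx[sel] == s]
      if (length(here) > 0L) {
        out[here] <- sample.int(4L, length(here), replace = TRUE, prob = P[s, ])
      }
    }
  }
  out
}

# Codon-position maps used to veto nonsense mutations during evolution.
# Each element describes one CDS: `P` is an (n_codons - 1) x 3 matrix of
# 1-based positions into the evolved vector, rows in translation order
# (terminal stop codon excluded); `minus` marks genes read off the reverse
# strand (positions descend; bases are complemented for codon decoding).
make_cds_map <- function(starts, ends, strands) {
  map(seq_along(starts), function(i) {
    pos <- (starts[i] + 1L):ends[i]
    if (strands[i] == "-") pos <- rev(pos)
    P <- matrix(pos, ncol = 3L, byrow = TRUE)
    P <- P[-nrow(P), , drop = FALSE]  # terminal stop codon may stay a stop
    list(P = P, minus = strands[i] == "-")
  })
}

STOP_CODES <- c(48L, 50L, 56L)  # TAA, TAG, TGA as (i1-1)*16+(i2-1)*4+(i3-1)

# Revert codons that mutated into internal stops back to the parent state
# (purifying selection against nonsense mutations). The parent is stop-free
# by induction, so the repaired child is too.
repair_stops <- function(parent, child, cds_map) {
  if (is.null(cds_map)) return(child)
  for (cm in cds_map) {
    M <- matrix(child[cm$P], nrow = nrow(cm$P))
    if (cm$minus) M <- 5L - M
    code <- (M[, 1L] - 1L) * 16L + (M[, 2L] - 1L) * 4L + (M[, 3L] - 1L)
    bad <- which(code %in% STOP_CODES)
    if (length(bad) > 0L) {
      sel <- cm$P[bad, , drop = FALSE]
      child[sel] <- parent[sel]
    }
  }
  child
}

# Evolve a root state vector along a phylo tree; returns a list of tip index
# vectors named by tip label. `site_scale` optionally multiplies branch
# lengths per site (same mask on every branch); `cds_map` vetoes internal
# stop codons per branch.
evolve_tree_idx <- function(root_idx, tree, model, site_scale = NULL,
                            cds_map = NULL) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- vector("list", n_node)
  root <- n_tip + 1L
  states[[root]] <- root_idx
  el <- tree$edge.length %||% rep(0, nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1L]; chi <- tree$edge[k, 2L]
    t_eff <- el[k] * model$rate
    tvec <- if (is.null(site_scale)) t_eff else t_eff * site_scale
    child <- evolve_branch_idx(states[[par]], tvec, model)
    states[[chi]] <- repair_stops(states[[par]], child, cds_map)
  }
  setNames(states[seq_len(n_tip)], tree$tip.label)
}

#' Evolve a root sequence along a tree under an HKY model
#'
#' Sites are independent; each branch applies the model's transition
#' probabilities for its (rate-scaled) length.
#'
#' @param root Root nucleotide sequence (A/C/G/T only).
#' @param tree An `ape::phylo` tree with branch lengths in substitutions/site.
#' @param model An [hky_model()].
#' @param seed Integer seed; the same seed reproduces the same tips.
#' @return A named character vector of tip sequences.
#' @export
evolve_sequence <- function(root, tree, model = hky_model(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!nzchar(root)) abort("root sequence must be non-empty")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("branch lengths must be non-negative")
  }
  idx <- nt_to_idx(root)
  tips <- with_seed(seed, evolve_tree_idx(idx, tree, model))
  vapply(tips, idx_to_nt, character(1))
}
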