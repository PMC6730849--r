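# Independent oracles used by the test suite. These deliberately re-derive
# results by brute force or closed form, separately from the package code.

# --- exhaustive global alignment score (affine gaps) ------------------------
# Enumerates all alignments recursively in state space (position, position,
# previous-move) for tiny inputs.
oracle_global_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > length(ca) && j > length(cb)) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      cost <- gap_extend + if (prev == "x") 0 else gap_open
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j <= length(cb)) {
      cost <- gap_extend + if (prev == "y") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "m")
}

# Full-matrix local alignment (independent Gotoh written in plain R).
oracle_local_score <- function(a, b, sub, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      diag <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0)
      M[i, j] <- diag + sub[ca[i - 1], cb[j - 1]]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- six-frame pheromone scan oracle ---------------------------------------
# Anchored pattern check on every ORF of every frame, written around regex
# and Biostrings::translate rather than the package's scanner.
oracle_pheromone_scan <- function(seq, min_spacer = 15, max_spacer = 60) {
  hits <- list()
  scan_strand <- function(s, strand, n) {
    for (f in 0:2) {
      nc <- nchar(s)
      usable <- nc - f
      usable <- usable - usable %% 3
      if (usable < 6) next
      subseq <- substr(s, f + 1, f + usable)
      if (grepl("[^ACGT]", subseq)) {
        # translate codon-wise, marking ambiguous codons
        cods <- substring(subseq, seq(1, usable - 2, 3), seq(3, usable, 3))
        aa <- vapply(cods, function(cd) {
          if (grepl("[^ACGT]", cd)) "?" else
            as.character(Biostrings::translate(Biostrings::DNAString(cd)))
        }, character(1))
      } else {
        aa <- strsplit(as.character(
          Biostrings::translate(Biostrings::DNAString(subseq))), "")[[1]]
      }
      prot <- paste(aa, collapse = "")
      # each M ... first following stop
      for (mpos in gregexpr("M", prot, fixed = TRUE)[[1]]) {
        if (mpos < 0) next
        rest <- substr(prot, mpos, nchar(prot))
        stop_rel <- regexpr("[*?]", rest)
        if (stop_rel < 0) next
        if (substr(rest, stop_rel, stop_rel) == "?") next
        pep <- substr(rest, 1, stop_rel - 1)
        L <- nchar(pep)
        if (L < min_spacer + 5 || L > max_spacer + 5) next
        if (!grepl("^M.*C[ILMVST][ILMVST].$", pep)) next
        if (substr(pep, L - 3, L - 3) != "C") next
        start_nt <- f + (mpos - 1) * 3          # 0-based on this strand
        end_nt <- f + (mpos - 1 + L + 1) * 3    # includes stop codon
        if (strand == "+") {
          hits[[length(hits) + 1]] <<- data.frame(
            start = start_nt, end = end_nt, strand = strand, peptide = pep)
        } else {
          hits[[length(hits) + 1]] <<- data.frame(
            start = n - end_nt, end = n - start_nt, strand = strand,
            peptide = pep)
        }
      }
    }
  }
  n <- nchar(seq)
  scan_strand(toupper(seq), "+", n)
  scan_strand(matloci::revcomp(seq), "-", n)
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), peptide = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# --- NG86 path-enumeration oracle ------------------------------------------
# Independent enumeration over orderings using explicit permutation tables.
oracle_ng86 <- function(codon_a, codon_b) {
  code <- Biostrings::GENETIC_CODE
  ca <- strsplit(codon_a, "")[[1]]; cb <- strsplit(codon_b, "")[[1]]
  syn_sites <- function(cc) {
    aa <- code[paste(cc, collapse = "")]
    tot <- 0
    for (p in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), cc[p])) {
        mut <- cc; mut[p] <- nb
        maa <- code[paste(mut, collapse = "")]
        if (maa != "*" && maa == aa) tot <- tot + 1 / 3
      }
    }
    tot
  }
  dpos <- which(ca != cb)
  if (length(dpos) == 0) {
    return(list(s_a = syn_sites(ca), s_b = syn_sites(cb), Sd = 0, Nd = 0))
  }
  perms <- switch(length(dpos),
                  list(1),
                  list(c(1, 2), c(2, 1)),
                  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                       c(3, 1, 2), c(3, 2, 1)))
  evals <- lapply(perms, function(ord) {
    cur <- ca; syn <- 0; non <- 0; blocked <- FALSE
    for (p in dpos[ord]) {
      nxt <- cur; nxt[p] <- cb[p]
      a1 <- code[paste(cur, collapse = "")]
      a2 <- code[paste(nxt, collapse = "")]
      if (a2 == "*" && !all(nxt == cb)) blocked <- TRUE
      if (a1 != "*" && a2 != "*" && a1 == a2) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non, blocked)
  })
  m <- do.call(rbind, evals)
  keep <- m[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(m))
  list(s_a = syn_sites(ca), s_b = syn_sites(cb),
       Sd = mean(m[keep, 1]), Nd = mean(m[keep, 2]))
}

# --- minimum monotone-partition oracle for synteny blocks -------------------
# Exhaustively enumerates all contiguous partitions (2^(n-1) compositions)
# and returns the minimum number of valid runs; a run is valid when
# orientation is constant and pos_b strictly monotone in the direction the
# orientation implies.
oracle_min_partition <- function(anchors) {
  n <- nrow(anchors)
  valid_run <- function(idx) {
    ori <- unique(anchors$rel_orientation[idx])
    if (length(ori) != 1) return(FALSE)
    if (length(idx) == 1) return(TRUE)
    pb <- anchors$pos_b[idx]
    if (ori == "same") all(diff(pb) > 0) else all(diff(pb) < 0)
  }
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    ok <- TRUE
    for (k in seq_len(length(bounds) - 1)) {
      idx <- (bounds[k] + 1):bounds[k + 1]
      if (!valid_run(idx)) { ok <- FALSE; break }
    }
    if (ok) best <- min(best, length(bounds) - 1)
  }
  best
}

# --- random additive tree + distance matrix --------------------------------
random_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}
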