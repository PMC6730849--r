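# Shared fixtures, built once per test run.

sim_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small A1/A2/A2 one-species trio, reused by several test files.
cached_trio_sim <- function() {
  if (is.null(sim_cache$trio)) {
    sim_cache$trio <- simulate_dataset(sim_config(
      n_species = 1L, strains_per_species = c("A1", "A2", "A2"),
      seed = 20260921L))
  }
  sim_cache$trio
}

# An A1/A2 pair without background contigs (synteny-focused tests).
cached_pair_sim <- function() {
  if (is.null(sim_cache$pair)) {
    sim_cache$pair <- simulate_dataset(sim_config(
      n_species = 1L, strains_per_species = c("A1", "A2"),
      n_background_contigs = 0L, seed = 480L))
  }
  sim_cache$pair
}

mat_region_annotation <- function(sim, strain) {
  ann <- sim$annotations[[strain]]
  ann[ann$contig == sim$truth$mat_contig, ]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, n, replace = TRUE), collapse = "")
}

mk_anchor_tbl <- function(pos_b, ori) {
  tibble::tibble(
    gene_a = sprintf("a%02d", seq_along(pos_b)),
    gene_b = sprintf("b%02d", seq_along(pos_b)),
    pos_a = seq_along(pos_b) * 1000,
    pos_b = pos_b,
    strand_a = "+",
    strand_b = ifelse(ori == "same", "+", "-"),
    rel_orientation = ori,
    score = 100)
}
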