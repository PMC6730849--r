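---
title: "Detecting and characterizing fused fungal MAT loci with matloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing fused fungal MAT loci with matloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matloci)
```

## The biological problem

Many basidiomycete yeasts determine mating compatibility at two loci: the
P/R locus, carrying a pheromone receptor (STE3) and one or more short
lipopeptide pheromone precursor genes (MF), and the HD locus, carrying
homeodomain transcription factors (SXI1, an HD1-class gene, or SXI2, an
HD2-class gene). In the Trichosporonales these two loci are fused into a
single region: pheromone and receptor sit at one end, a single HD gene at
the other, roughly 55 kb apart, with a conserved set of companion genes
(STE20, IKS1, STE11, MYO2, RPL22) in between. Two allele classes circulate;
they are named for the STE3 variant they carry (A1 for STE3&alpha;, A2 for
STE3**a**), with the "starred" variants A1\*/A2\* carrying the alternative
SXI gene (A1 = STE3&alpha;+SXI2, A2 = STE3**a**+SXI1, A1\* =
STE3&alpha;+SXI1, A2\* = STE3**a**+SXI2). The two classes differ by two
inversions, one of which spans most of the core region.

A fused region inherited as one unit is a supergene: recombination between
the mating-type-defining genes is suppressed. Three signatures are expected
and each has a dedicated analysis in this package:

* **Trans-species polymorphism.** If the STE3 allele classes diverged
  before the species did, STE3 genealogies cluster strains by mating type
  across species instead of by species. `pairwise_distances()`,
  `nj_tree()` and `classify_clustering()` formalize this as a bipartition
  test on the unrooted tree.
* **Elevated between-type divergence in the core region.** If exchange
  between A1 and A2 is suppressed, synonymous divergence (dS) between
  strains of opposite mating type should exceed dS between strains of the
  same mating type for genes inside the region. `estimate_ds()` implements
  Nei–Gojobori (1986) counting with Jukes–Cantor correction;
  `compare_ds_sets()` runs the one-sided pooled-variance t-test;
  `closest_pair_calls()` reproduces the three-strain "most similar pair"
  coloring.
* **Composition drift.** A region that stopped recombining accumulates the
  AT bias of spontaneous mutation. `gc_windows()` (2-kb windows),
  `cds_gc()` and `rscu()` quantify it; `rank_sum_test()` supplies the
  regional contrast.

The structural analyses — `scan_pheromones()` for the
M–X(15–60)–C–[ILMVST]–[ILMVST]–X–Stop consensus, `assign_roles()`
(reciprocal best hit against a reference panel), `locate_mat()` and
`classify_allele()`, `anchor_map()`/`detect_blocks()` for inversion
breakpoints, and `window_similarity()` for 1-kb BLASTN-like score tracks —
identify the locus and its architecture in the first place.

## The synthetic-genome generator

Real fused MAT regions come with full genome assemblies attached, so the
package validates itself on synthetic panels whose ground truth is known
exactly. `simulate_dataset()` plants every structure the detectors look
for, and returns a complete truth record (`$truth`) holding the species
tree, allele classes, all coordinates, the planted inversion segments and
their bounding intergenic gaps.

The generator works gene-by-gene on an ancestral layout:

* **Template.** 22 genes: MF, STE3, the five companions, 14 filler genes
  (lengths drawn uniformly on 900–2400 nt) and the HD slot, with
  intergenic gaps uniform on 200–2000 nt. The filler count is set so the
  expected STE3-to-HD gap is about 55 kb. Two inversion segments (gene
  indices 3–17 and 19–21 by default, the first spanning most of the core
  region) are reverse-complemented in A2-type strains, so the A1 and A2
  coordinate systems agree everywhere except inside the segments.
* **Evolution.** Sites evolve independently under an HKY model
  (&kappa; = 2) with the equilibrium GC of their compartment. Branch
  lengths are in substitutions/site. Coding regions are protected against
  nonsense mutations: a codon that would become an internal stop reverts
  to its parent state on that branch, a minimal stand-in for the
  purifying selection real genes experience. Indels are not simulated,
  which keeps truth coordinates exact and every ortholog alignment
  columnar.
* **Mating types.** The core region's ancestral sequence splits into two
  class alleles along two branches of `mat_suppression_extra / 2` each
  (default total 0.02 substitutions/site, applied only between mating
  types and only inside the core region). STE3 instead descends from a
  two-allele gene tree of depth `ste3_allele_depth` (default 0.5, far
  older than the default species-tree height of 0.2), which makes its
  genealogy trans-specific. SXI1 and SXI2 are two distinct genes, not
  alleles: each strain carries the one its class dictates, in the same
  genomic slot. The pheromone CDS is planted per mating type and held
  fixed rather than evolved: the consensus is a hard functional
  constraint, and free evolution of a ~60-codon CDS would sporadically
  destroy the planted motif the scanner is being tested against.
* **Composition.** The core region uses `mat_gc = background_gc - 0.08`
  (default background 0.60, inside the 58–63% genomic GC typical of these
  yeasts); flanks and background contigs (which carry the control genes
  for genealogy screens) use the background GC.
* **Suspension bridge.** With `homogenize_interior = TRUE` the
  between-type extra divergence is scaled by `interior_factor` (0.25) for
  sites deeper than `edge_zone` (3 kb) inside an inversion, mimicking
  gene-conversion-like homogenization of inversion interiors. The
  1-kb similarity track then dips at the breakpoints relative to the
  interiors — the suspension-bridge pattern. This is off by default and
  switched on for the breakpoint-divergence analyses.

Default panel: three species, each with one A1 and one A2 strain.
`tree_height` defaults to 0.2 substitutions/site; this clade is deeply
diverged, and a much shallower tree would place species splits inside the
noise floor of the intraspecific divergence (`within_species_depth`,
0.005 per strain branch, i.e. ~1% between strains of a species).

What the generator deliberately does **not** emulate: indels and
rearrangements outside the planted inversions, repeats and transposable
elements, gene gain/loss, rate heterogeneity across sites, and assembly
artifacts. Passing the recovery studies therefore shows the estimators and
detectors are correct under their stated models, not that they are robust
to every feature of real assemblies.

## Numerical and procedural choices

* **dS estimation.** NG86 counting: per-codon synonymous site fractions
  (mutations to stop codons count as nonsynonymous), difference counts
  averaged over all orderings of the differing positions with
  stop-crossing orderings excluded (all-blocked pairs fall back to
  including them). Jukes–Cantor correction
  $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$; estimates with
  $p \ge 3/4$ are reported as undefined ("Un" in tables). Standard errors
  come from a seeded codon-resampling bootstrap (default B = 1000) rather
  than an analytic variance: it is distribution-free and directly
  testable. The codon alignment is protein-guided (global alignment of
  the translations, back-translated onto codons), which preserves frame
  by construction.
* **Alignment scoring.** BLOSUM62 with gap open 11 / extend 1 for
  proteins; match +2 / mismatch −3, gap open 5 / extend 2 for
  nucleotides — the conventional BLAST parameterizations. A gap run of
  length $k$ costs open + $k\cdot$extend. Where only scores are needed
  (reciprocal-best-hit matrices, window tracks, closest-pair calls) a
  compiled score-only Gotoh engine is used; its scores are asserted equal
  to `Biostrings::pairwiseAlignment` in the test suite. Tracebacks go
  through Biostrings.
* **Role assignment.** Reciprocal best hit on alignment score (score is
  length-aware; identity is reported and used only as a floor, default
  score ≥ 50 and identity ≥ 0.25). Ties are flagged and broken by
  lexicographic gene id. The STE3 a/&alpha; call takes the best-scoring
  reference class with a 5%-of-score unresolved margin; the conserved
  &alpha;-group N-terminal proline is reported as an advisory flag only.
* **Pheromone scan.** Any-ATG ORFs to the first in-frame stop, standard
  genetic code, both strands, peptide length 20–65; ORFs containing
  ambiguity codes are skipped. The consensus anchors the CaaX cysteine at
  the fourth-from-last residue. The motif is permissive: on realistic
  sequence it chance-matches roughly once per 15–20 kb per strand, so a
  55-kb region essentially always carries spurious hits. The scanner
  reports everything (and is tested against a six-frame brute-force
  oracle); the pipeline identifies *the* MAT pheromone gene as the hit
  nearest STE3.
* **Synteny.** Anchors at gene midpoints; an inversion must flip both
  order and strand. Blocks are greedy maximal runs of constant
  orientation and monotone partner position; because run validity is
  closed under contiguous subsequences, the greedy partition is provably
  minimal, and the suite checks it against exhaustive enumeration on
  small inputs. Runs below `min_anchors = 2` are excluded as singletons,
  which keeps single-gene transpositions from being called inversions.
  Breakpoints are the open intervals between the outermost anchors of
  adjacent blocks.
* **Rank-sum test.** Mann–Whitney with midranks. For
  $n_1 n_2 \le 400$ the p-value is exact, from a generating-function DP
  over the observed (doubled) midranks, which handles ties exactly —
  something `wilcox.test` cannot do; above that a normal approximation
  with tie and continuity corrections is used. The two methods agree to
  0.01 at the boundary, and `wilcox.test` is the cross-check in the
  no-ties case.
* **Genealogies.** JC distances with pairwise deletion, neighbor joining
  (via `ape::nj`, with negative branches clamped to zero and the deficit
  moved to the sister branch), and a strict bipartition rule: a tree is
  `mating_type` if some split separates the two allele classes exactly,
  `species` if no such split exists and every multi-tip species is
  separated by some split, otherwise `mixed`. The rule is invariant to
  rerooting and tip order. Visual "branching by mating type" has no
  canonical formalization; the strict bipartition is conservative.
* **t-test gene set.** The trio analysis excludes the mating-type-defining
  genes (MF, STE3, SXI) from the t-test: SXI genes are not alleles of one
  another, and the ancient STE3 divergence would dominate the statistic;
  in the real data those genes drop out as undefined ("Un") estimates.
  They remain in the per-gene dS table.
* **Breakpoint-divergence test.** Windows overlapping a detected
  breakpoint interval (±2 windows) versus windows inside inverted blocks;
  one-sided rank-sum for lower breakpoint similarity. Note that the
  1–2 windows straddling an inversion junction score lower even without
  any homogenization, because their best local alignment cannot span the
  junction; the planted-homogenization contrast is the designed use.

## Problem sizes used in validation

The recovery studies simulate: 100 A1/A2 pairs for inversion recovery
(50 in the acceptance script);
50 suppression and 50 null trios for the dS t-test (plus 25 + 25 in the
acceptance script); 20 six-strain panels for the trans-species screen
(12 in the script); 50 pairs for the composition contrast (25 in the
script); 2000 null draws for test calibration; 200 random additive
8-taxon matrices for NJ; all 3721 ordered sense-codon pairs for the NG86
oracle; 500 random 10-kb sequences plus 100 planted ORFs for the scanner
oracle. These sizes give the proportions being thresholded (e.g. a 95%
recovery bound over 100 replicates) enough resolution to be meaningful
while keeping a full run of the suite on a laptop comfortable.

## A worked example

```{r example, eval = FALSE}
library(matloci)

# a one-species trio: one A1 strain, two A2 strains
sim <- simulate_dataset(sim_config(
  n_species = 1, strains_per_species = c("A1", "A2", "A2"), seed = 1))

report <- run_characterize(sim, seed = 1)
glance(report)

# per-strain locus reports: linkage, P/R-to-HD distance, allele class
dplyr::select(report$reports, genome_id, linked, distance_bp, allele)

# the two planted inversions
tidy(report$synteny$blocks)

# dS contrast between vs within mating type
report$divergence$ttest
autoplot(report$synteny$track)
```

## Known limitations

* The NG86/JC estimator is downward-biased at high divergence relative to
  maximum-likelihood codon models; the pipeline targets the low-divergence
  regime (within-genus comparisons) where the two agree closely.
* Ortholog assignment is reciprocal-best-hit without synteny-aware rescue;
  tandem duplicates anchor only one copy.
* The allele classification requires a resolved STE3 type and a single HD
  gene; hybrid assemblies are split by contig, not phased.
* No repeat masking or indel handling: on real assemblies, regions rich in
  repeats should be masked upstream, and the columnar codon alignment
  assumes annotation-quality CDS models.
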