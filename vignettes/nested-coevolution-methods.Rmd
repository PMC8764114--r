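---
title: "Nested coevolution: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested coevolution: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcoev)
```

## The problem and the model

Columns of a protein multiple sequence alignment covary for two distinct
reasons. Residues that interact — structurally or functionally — accumulate
compensatory substitutions, which is the signal coevolution methods are
after. But columns also covary because the sequences share a phylogeny:
substitutions fixed in a common ancestor appear simultaneously in all of
its descendants, so any pair of columns that changed on the same deep
branch looks coupled when sequences from different subtrees are compared.
Corrections such as the average product correction (APC) attack this
confound heuristically; nested coevolution (NC) attacks it with an explicit
null model.

The construction has three ingredients.

1. **Total covariation.** The default metric is normalized mutual
   information, `C_T(i, j) = (H_i + H_j - H_ij) / H_ij`, in nats, from
   unweighted empirical column frequencies over the 20 canonical amino
   acids. Dividing MI by the joint entropy removes its dependence on
   per-column conservation. Mean-field DCA (direct information or the
   Frobenius norm of zero-sum-gauge couplings) can be substituted.

2. **Clades.** Sequences closer than a Jukes–Cantor distance `d` are
   grouped; we take connected components of the `< d` graph (single
   linkage), which is the only reading of "all sequences within distance
   d" that yields a proper partition for arbitrary `d`. The 20-state
   protein Jukes–Cantor form `d = -(19/20) ln(1 - (20/19) p)` converts the
   mismatch fraction `p` into an expected substitutions-per-site distance.

3. **The within-clade resampling null.** Redrawing every symbol, per
   column and per sequence, from that sequence's own clade preserves each
   clade's column compositions — and therefore every between-clade
   difference — while destroying all within-clade column–column coupling.
   The metric averaged over such resamples, `C_{S>d}`, is the covariation
   phylogeny alone explains at scales coarser than `d`, and
   `C_{S<=d} = C_T - C_{S>d}` is the nested-coevolution matrix. For NMI
   the null has a closed form: the null joint distribution of a column
   pair is the clade-size-weighted mixture of products of clade marginals,
   so the null NMI is assembled from the unchanged marginal entropies and
   the mixture joint entropy. For DI/Frobenius no closed form exists and
   the bootstrap is used, re-deriving DCA sequence weights on every
   resample so the null is processed exactly like the observed data.

The NC matrix is a signed difference and is deliberately left unclipped:
entries below zero mean the observed coupling is weaker than phylogeny
predicts, and ranking operations consume the signed values.

Assumptions worth stating: columns are treated as independent within
clades under the null (epistasis between more than two positions is not
modeled); the clade partition is taken as known once `d` is fixed; and the
alignment is assumed gap-free after preprocessing, so all sums run over
exactly 20 states.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| phylogenetic cutoffs | 0.2, 0.5, 0.8, 1.1 | JC substitutions/site | span the intra- to inter-family range left after reference pruning at distance 1 |
| gap-column threshold | 25% | fraction | columns gappier than this carry little comparable signal |
| reference pruning | JC > 1 | distance | removes homologs too diverged for reliable column correspondence |
| DCA pseudocount λ | 0.5 | relative weight | `f~ = (1-λ) f + λ/q`; heavy regularization keeps the mean-field inversion stable |
| DCA reweighting | 0.3 | Hamming fraction | sequences closer than this share a weight unit |
| contact threshold | 5 (8 alt.) | Å, CA–CA | standard contact definitions |
| sequence separation | \|i−j\| > 5 | residues | excludes trivial backbone-neighbor contacts |
| top-k contacts | 50 | pairs | conventional evaluation depth |
| sector pairing | \|dot\| > 0.6 | — | eigenvector correspondence threshold |
| minimum sector size | 4 | residues | smaller coefficient sets are noise (`ignored` flag) |
| bootstrap replicates | 100 | — | significance resolution 0.01; 200 used in the validation suite |
| random-group null | 1000 | groups | stabilizes mean/SD and the 2.5/97.5 percentiles |

The DI fixed point (compensating fields of the two-site model) iterates to
a tolerance of 1e−6 with a 200-iteration cap; non-converged pairs keep the
last iterate and are counted in a warning. The mean-field inversion drops
the 20th symbol per position (q−1 states) and re-expands couplings in the
zero-sum gauge for the Frobenius score. "Pseudocount 0.5" is read as a
relative mixture weight; the alternative convention (weight relative to
the effective sequence number) sits behind the same single parameter.

## Numerical and tie-breaking choices

* Entropies are computed from integer count tables via `n log n` sums, so
  `H = log N - sum(n log n)/N` is exact up to floating-point addition;
  tiny negative MI values from cancellation are clipped to 0 and NMI is
  clamped to [0, 1].
* Saturated sequence pairs (mismatch ≥ 19/20, where the JC log diverges)
  are capped at distance 10 with a warning; preprocessing makes them rare.
* Pair ranking breaks ties lexicographically by `(i, j)`; clade labels are
  assigned in order of each component's lowest row index; gap-fill donor
  ties go to the lowest row index — all so that reruns and alternative
  BLAS backends give identical output.
* Eigenvectors are oriented so the maximum-|coefficient| entry is
  positive; sector pairing uses |dot| and is therefore orientation-free.
  The supermatrix covariance divides by the number of stacked rows
  (population form), which makes the spectrum of `n` identical stacked
  matrices exactly equal the single-matrix spectrum — the identity that
  pins down the centering semantics.
* `dominant_sector()` chooses between the two signed sectors of an
  eigenvector by the magnitude of the size-th ranked coefficient: a real
  sector is a coherent block of comparable coefficients, while the
  opposite side of the eigenvector is typically a diffuse tail (often
  anticorrelated background induced by APC).
* The APC row/column means exclude the diagonal, whose NMI is identically
  1 and would otherwise bias the correction.

## What the synthetic generator emulates — and what it does not

`simulate_clade_msa()` draws a star-of-clades: a uniform random root, one
ancestor per clade (per-site mutation probability `mu_inter`, optionally
one value per clade), and leaves mutated from their ancestor at `mu_intra`
(optionally a per-leaf rate drawn from a range). Three signals can be
planted:

* **confound groups** mutate in lockstep at the ancestor step only — the
  inter-clade covariation NC is designed to subtract;
* **coupled pairs** tie leaf mutations together through fixed
  complementary-symbol permutations with probability `coupling_rho` —
  true within-clade coevolution;
* **divergent columns** follow an independent random partition of the
  sequences, producing a position group whose phylogeny disagrees with
  the rest of the protein (a planted low-MirrorTree sector).

Default conditions (4 clades x 50 leaves, p = 50, `mu_inter = 0.3`,
`mu_intra = 0.08`, `coupling_rho = 0.9`) put intra-clade distances near
0.16 and inter-clade distances near 0.8 — inside the default cutoff grid
and below the reference-pruning threshold of 1. Three validation regimes
deviate deliberately:

* the **confound-rejection** experiment uses 8 clades, because with only
  4 ancestors the lockstep groups do not dominate raw NMI and there is no
  confound to reject;
* the **MirrorTree calibration** uses 3 clades of 70 leaves at depths
  (0.15, 0.3, 0.45) with per-leaf rates U(0.005, 0.1). With equal-depth
  clades all inter-clade distances coincide, and the Pearson correlation
  between 15-column and full-alignment distances is capped near 0.84 by
  binomial sampling noise; varied depths and branch-rate heterogeneity
  spread the distance distribution continuously, as in real families, and
  random 15-residue groups then score above 0.9;
* the **end-to-end sector** experiment couples all pairs of the
  15-position sector (the sector coevolves as a unit): a sparse coupling
  graph leaves the supermatrix covariance of sector columns too weak for
  the leading eigenvector to collect them.

What the generator does **not** emulate: realistic substitution matrices
(exchanges are uniform over the other 19 symbols), indels and alignment
error, site-specific conservation profiles, hierarchical tree shapes
beyond the star of clades, and couplings beyond pairwise complementary
maps. Passing the validation suite therefore demonstrates correctness of
the machinery and recoverability of planted signal under controlled
conditions — not performance on real families, whose alignments are
deeper, longer, and phylogenetically far more structured.

`simulate_potts_msa()` Gibbs-samples sequences from an explicit pairwise
model (independent chains per sequence, vectorized site updates) and is
the ground truth for the DCA implementation. `simulate_structure()` builds
a CA trace as a 3.8 Å-step random walk with excluded volume (minimum CA–CA
distance 3.4 Å) and a look-ahead constraint that keeps designated sector
residues inside a ball of the requested radius without breaking the exact
step length.

## Problem sizes in the validation suite

The suite and the acceptance script run on one CPU in well under a minute
each with: a 200 x 50 two-clade fixture (200 bootstrap replicates for the
null-agreement and significance checks), ten 400 x 50 eight-clade
alignments for confound rejection, ten 500 x 20 Potts samples for the DCA
oracle, 100 random 25 x 25 matrices for the contact-scoring brute-force
comparison, 210 x 50 alignments with 1000 random groups for MirrorTree
calibration, and ten end-to-end runs (200 x 50 before preprocessing) with
1000-group compactness nulls. These sizes were chosen to keep Monte-Carlo
error comfortably inside the asserted margins while remaining desk-scale.

## Open design decisions

* Whether the published analyses applied APC before or after the NC
  subtraction for contact prediction is not determinate; both orders are
  available, and sector discovery defaults to NC first, then APC, inside
  the supermatrix step.
* The clade definition (single linkage at `< d`) is one of several
  readings of distance-threshold clades; it is recorded as this package's
  choice, not an inference about other implementations.
* The number of "significant" eigenvectors is a user parameter
  everywhere; no automatic significance rule is imposed.
* The high-conservation pre-filter (entropy < 0.1) mentioned in the
  sector literature is available in spirit via `random_group_null()`'s
  entropy-matched sampling but is not applied before eigendecomposition.

## Known limitations

* The analytical null exists only for NMI; DI/Frobenius nulls cost one
  full DCA fit per bootstrap replicate.
* All-pairs NMI uses a dense `20p x 20p` count matrix (~3 GB at
  p = 700), so very long proteins need blocking that is not implemented.
* Single-linkage clades can chain distinct groups together through
  intermediate sequences when the alignment is short (noisy distances) —
  visible in the generator itself at p = 50 with many clades.
* `preprocess_msa()` is idempotent on realistic inputs, but gap filling
  uses pre-fill distances, so pathological alignments dominated by gaps
  can shift distances slightly on a second pass.
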