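# nestcoev

Coevolution analysis of protein multiple sequence alignments (MSAs) is
confounded by phylogeny: positions that changed together in a common
ancestor look statistically coupled in every descendant comparison, whether
or not they interact functionally. `nestcoev` implements a **nested
coevolution (NC)** correction that separates this inter-clade signal from
genuine intra-clade covariation, together with the downstream analyses that
consume the corrected matrices: structural contact prediction, sector
discovery by eigendecomposition, phylogenetic-distinctness scoring of
sectors, and deep-mutational-scanning overlays. It is aimed at
computational biologists studying residue coupling, protein sectors and
their functional interpretation.

## The method

Given an aligned, gap-free MSA, total covariation between columns *i* and
*j* is measured with the normalized mutual information

C<sub>T</sub><sup>ij</sup> = (H<sub>i</sub> + H<sub>j</sub> −
H<sub>ij</sub>) / H<sub>ij</sub>,

where H<sub>i</sub> is the Shannon entropy of column *i* and H<sub>ij</sub>
the joint entropy (normalization by H<sub>ij</sub> removes the dependence
of mutual information on conservation). Sequences are partitioned into
clades — connected components of the graph joining pairs whose Jukes–Cantor
distance is below a cutoff *d* — and the covariation expected from
phylogeny alone, C<sub>S>d</sub>, is estimated by averaging the metric over
alignments resampled **within clades** (every symbol redrawn from its own
clade's column), or in closed form for NMI via the mixture joint

p<sup>null</sup><sub>i=k,j=l</sub> = Σ<sub>c</sub> n<sub>c</sub>
p<sup>c</sup><sub>i=k</sub> p<sup>c</sup><sub>j=l</sub> / Σ<sub>c</sub>
n<sub>c</sub>.

The nested coevolution matrix at cutoff *d* is the signed difference

C<sub>S≤d</sub><sup>ij</sup> = C<sub>T</sub><sup>ij</sup> −
C<sub>S>d</sub><sup>ij</sup>,

the covariation attributable to sequence comparisons *within* clades.
Computing it across several cutoffs (default 0.2, 0.5, 0.8, 1.1) resolves
coevolution by phylogenetic timescale; stacking the per-cutoff matrices
into a supermatrix and eigendecomposing its column covariance yields
low-noise eigenvectors whose extreme coefficients define **sectors**.
Mean-field DCA (direct information and Frobenius-norm scores, pseudocount
0.5, 0.3-Hamming reweighting) and the average product correction are
provided both as baselines and as alternative metrics under the bootstrap
null. A repurposed MirrorTree score — the Pearson correlation between the
Jukes–Cantor distance matrices of the sector-filtered and full alignments —
quantifies how phylogenetically distinct a sector is.

## Worked example

Simulate a clade-structured alignment with a planted 15-residue sector
(positions 31–45) coevolving as a unit within clades, run the full NC
pipeline, and check what comes out:

```r
library(nestcoev)
sector <- 31:45
sim <- simulate_clade_msa(coupled_pairs = t(combn(sector, 2)), seed = 7)
msa <- preprocess_msa(sim$msa)
nc  <- nc_correct(msa, cutoffs = c(0.2, 0.5, 0.8, 1.1),
                  metric = "nmi", null_mode = "analytical")
spec <- nc_supermatrix_spectrum(nc)
sec  <- dominant_sector(spec, 1, 15)
sec
#> <sector> eigenvector 1 (negative), 15 positions: 42, 44, 45, 34, 36, 35,
#>   39, 31, 37, 40, 38, 33, 41, 43, 32
length(intersect(sec$positions, sector))
#> [1] 15
```

The leading supermatrix eigenvector recovers all 15 planted positions. The
sector's diagnostics against 1000 random 15-residue groups, using a
simulated structure in which the planted sector is spatially clustered:

```r
coords <- simulate_structure(50, sector_positions = sector,
                             cluster_radius_A = 8, seed = 7)
rg  <- random_group_null(msa, size = 15, n_samples = 1000, seed = 7,
                         coords = coords)
obs <- spatial_compactness(sec, coords)
#> compactness: 7.49 A (random-group mean 16.49, z = -5.72)
mirrortree_score(msa, sec$positions)
#> <mirrortree_score> sector-protein: 0.3365   (z = -6.64 vs random groups)
```

A mean pairwise CA–CA distance of 7.5 Å against a random-group mean of
16.5 Å (z = −5.7) marks the sector as spatially compact, and its
sector-protein MirrorTree score of 0.34 (z = −6.6; random groups score
close to 1) marks it as phylogenetically distinct — the two signatures of a
genuine functional sector.

A thin command-line interface wraps the same functions
(`inst/scripts/nestcoev.R` with subcommands `preprocess`, `subsample`,
`clades`, `covary`, `nc`, `contacts`, `sectors`, `mirrortree`, `simulate`,
`pipeline`), and `run_pipeline()` drives end-to-end runs from a YAML/JSON
config with a reproducibility manifest.

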