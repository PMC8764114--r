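Package: nestcoev
Title: Nested Coevolution Analysis of Protein Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates inter-clade from intra-clade covariation in protein
    multiple sequence alignments using a phylogenetically stratified null
    model ("nested coevolution"). Sequences are partitioned into clades at a
    Jukes-Cantor distance cutoff; within-clade column resampling (or a
    closed-form null for normalized mutual information) gives the covariation
    expected from phylogeny alone, and its subtraction from the total signal
    isolates coevolution among closely related sequences. Includes baseline
    coevolution metrics (normalized mutual information, mean-field direct
    coupling analysis with direct-information and Frobenius-norm scores,
    average product correction), structural contact-map evaluation, sector
    discovery by eigendecomposition of multi-cutoff supermatrices,
    MirrorTree-based phylogenetic distinctness scores, meta-sector clustering,
    deep-mutational-scanning enrichment overlays, and generators for
    clade-structured synthetic alignments and toy structures with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
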