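Package: icShapeMaP
Title: Mutational-Profile RNA Structure Probing and Dicer Cleavage-Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-nucleotide RNA reactivity scores from mutational-profiling
    (MaP) sequencing of intact small RNAs: parses reverse-transcription mutations
    from aligned reads into eight event classes, derives NAI-minus-DMSO mutation-rate
    differences, and normalizes them into SHAPE-style reactivity profiles with
    coverage masking and replicate QC. Downstream analyses cover SHAPE-constrained
    minimum-free-energy secondary structure prediction with Deigan pseudo-energies,
    structure feature extraction (terminal loops, bulges) and model comparison,
    loop-centered reactivity-profile PCA and K-means clustering, RIP enrichment and
    Dicer cleavage scoring from count tables, and geometric classification of Dicer
    cleavage-site selection rules (loop counting and 59 Angstrom distance rules) on
    tertiary coordinate models. A synthetic-data module generates hairpin references,
    simulated MaP read sets, count tables with planted effects, and idealized helical
    coordinate models so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    Biostrings,
    Rsamtools,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'energy-params.R'
    'structures.R'
    'folding.R'
    'clustering.R'
    'dicer-rules.R'
    'differential.R'
    'mutation-profiling.R'
    'pdb-io.R'
    'reactivity.R'
    'sam-io.R'
    'synthetic-data.R'
    'workflow.R'
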