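---
title: "Methods: MaP reactivity scoring and Dicer cleavage-site analysis"
author: "icShapeMaP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MaP reactivity scoring and Dicer cleavage-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icShapeMaP)
```

# The measurement model

Mutational-profiling (MaP) structure probing treats every reverse-
transcription mutation on a full-length read as evidence that the underlying
nucleotide carried a chemical adduct, and an adduct as evidence that the
nucleotide was flexible (single-stranded) when the reagent was applied. The
package's model of the data is therefore deliberately simple:

* each read spans its whole reference (full-length library construction
  removes truncated cDNAs, so there is no 3′ information loss and no
  RT-stop signal to model);
* at each position, a read acquires a mutation independently with a
  probability that depends on the reagent condition and the position's
  pairedness;
* the mock (DMSO) library measures everything that is not reagent-induced:
  sequencing/RT error and endogenous modifications (m1A-like sites show up
  as high DMSO mutation rates and must be masked, not interpreted).

## Mutation parsing

Reads are walked against the reference via their CIGAR. Primitive events —
per-base mismatches, insertion ops, deletion ops — are collected, ambiguous
deletions in repeats are shifted to their 3′-most equivalent placement
(reverse transcriptase misincorporates at the modified base as it approaches
from 3′, so the 3′-most placement is the mechanistically sensible one), and
events separated by at most `mergeSpacer = 2` matched bases are merged.
Merged events are classified into eight classes: single mismatch/insertion/
deletion, homogeneous multi-variants, and heterogeneous "complex" events
labelled by their net reference-length change (net gain → complex-insertion,
net loss → complex-deletion, net zero → multi-mismatch). The merge distance
of 2 is a package choice — it makes the complex classes reachable while
keeping isolated SNV-like events separate — and is exposed as a parameter.
Reads with mapping quality 0 or secondary/supplementary flags are excluded;
soft-clipped bases contribute neither events nor coverage. Multi-nucleotide
events are counted at their 3′-most reference position.

## Reactivity scores

With $r_i$ = (all-class event count)/(coverage) per library,

$$s_i = \frac{r^{\mathrm{NAI}}_i - r^{\mathrm{DMSO}}_i}{f}.$$

Replicates are combined by summing counts and coverage *before* computing
rates — pooling reads weights deep replicates correctly, whereas averaging
per-replicate rates would not.

The normalization factor $f$ uses the boxplot convention common to SHAPE
post-processing: values above Q3 + 1.5·IQR are excluded (capped at 10% of
the usable positions, largest first), and $f$ is the mean of the top 10% of
the remainder — so a typical strongly reactive nucleotide scores ≈ 1.
Negative scores are kept in output files (they carry QC information) but are
treated as 0 wherever a pseudo-energy is computed. Profiles with fewer than
10 usable positions, or a non-positive $f$, are emitted fully missing with a
warning rather than silently rescaled.

Masking thresholds: coverage below 1000× (default) is masked — 2000× gives
very high-quality scores and is recommended when depth allows, while 500× is
a tolerable floor; DMSO rate above `maxBackground = 0.05` is masked as a
likely endogenous modification.

## Replicate QC

Replicate agreement is measured on mutation rates, not scores: replicates
are balanced to equal totals by seeded down-sampling (per-position
hypergeometric thinning, which preserves events ≤ coverage), all bases are
sorted by coverage, and Pearson correlations are computed in windows of 50
bases stepped by 10 along that ordering, for each coverage cutoff in
{500, …, 5000}. Median window correlation grows with the cutoff — the
criterion used to pick a depth target. Windows with zero variance are
skipped and counted.

## AUC evaluation

A profile's agreement with a reference structure is the ROC AUC of scores
predicting the unpaired state, computed by midranks (tied pairs count half)
with missing positions excluded. This convention makes AUC(−s) = 1 − AUC(s)
exact.

# SHAPE-constrained folding

The folding engine is a self-contained Zuker-style MFE dynamic program over
a simplified nearest-neighbor model: Turner-style stacking free energies for
Watson–Crick and GU pairs (the 6×6 table is symmetrized to respect
strand-reversal symmetry), length-indexed hairpin/bulge/internal-loop
initiation penalties extrapolated logarithmically (1.75·RT·ln(n/n₀)) beyond
the tabulated sizes, an affine multiloop cost (a = 3.4, b = 0.4 per branch,
c = 0 per unpaired nt), minimum hairpin loop 3, interior loops capped at 30
unpaired nt, no dangles, no coaxial stacking, no terminal-pair penalties;
37 °C, kcal/mol. The recurrences (V/M/M1/W, multiloops closed as M + M1 to
force two branches) are in C++ for the O(n³) core.

Reactivity enters as the Deigan pseudo-energy, added once per paired
nucleotide:

$$\Delta G_{\mathrm{SHAPE}}(i) = m\,\ln(s_i + 1) + b,
\qquad m = 1.8,\; b = -0.6 \text{ kcal/mol},$$

with $s_i < 0$ treated as 0 and missing $s_i$ contributing nothing. An
all-zero profile therefore shifts the total energy by exactly
$b \times (\text{paired count})$ without changing the optimum — a property
the tests verify by re-scoring.

Correctness is established by oracle equivalence: for hundreds of random
sequences up to length 14 (and an exhaustive two-letter sweep), the DP
optimum equals the minimum over *all* enumerated pseudoknot-free structures
scored by an independent loop-decomposition evaluator, with and without
random profiles. Ties between co-optimal structures are broken by a fixed
search order, making predictions deterministic.

This engine is intentionally small: no partition function, no suboptimal
ensembles, no pseudoknots. It reproduces the constraint *mechanism* at desk
scale; absolute energies should not be compared against full-parameter
folding engines.

## Structure features and comparison

The **terminal loop** is chosen by the central-loop rule: among hairpin
loops, the one whose center is nearest the sequence midpoint, ties broken by
larger loop then 5′-most. ("Central" is otherwise ambiguous for cloverleaf
structures; this rule gives hairpin-like substrates their apical loop and is
deterministic for tRNA-like shapes.) Arms are defined 5′ and 3′ of that
loop. Each maximal unpaired run is classified terminal loop, bulge (the
flanking pair partners are adjacent on the other strand), or internal loop;
dangling ends outside the outermost helix belong to no class.
`compareStructures` partitions positions into identical / single-stranded in
one model / paired with different partners — the difference taxonomy used to
contrast constrained and database structures.

# Differential scores

Enrichment and cleavage scores are plain log2 ratios of within-library read
proportions; the library total is the table's own sum (the upstream subset
used for normalization is not recoverable from a count table, so the table
defines it — recorded here as a package decision). Zero counts yield missing
scores rather than pseudocounted ones: classification only needs the sign of
observed transcripts, and a pseudocount would manufacture signs. A
`pseudocount` argument exists for exploration and is documented as
non-canonical. Note that because condition-B proportions are renormalized,
planting a large effect on a large-share transcript shifts every other
transcript's ratio by −log2(Σ p·2^e); recovery statements therefore hold for
effects on small-share transcripts (the benchmark plants effects on ~1%
shares, where the shift is < 0.08).

# Profile clustering

Profiles are aligned on the central-loop center (floor midpoint for even
loops) into 60 columns −30…−1, +1…+30 — the center nucleotide itself is
excluded, which is what makes the space exactly 60-dimensional. Positions
beyond the transcript and masked scores are imputed with the transcript's
mean score (the least structured choice; zero- and column-mean imputation
are available), and transcripts > 50% missing are dropped with a log entry.
PCA mean-centers but does not variance-scale — normalized reactivities
already share a scale, and variance-scaling would inflate flat flank
positions. Loading signs are fixed (largest-magnitude entry positive) so
runs are comparable. K-means uses Lloyd iterations with 10 restarts under a
seed, and labels are renumbered by descending cluster size. K = 3 reflects
the three substrate families the package's archetype generator emulates
(hairpin-like, loose-stem, cloverleaf-like); no automatic K selection is
attempted.

# Dicer cleavage-site rules

Cleavage sites are taken from the annotation: the 5′ end of the 3p miRNA
and the 3′ end of the 5p miRNA.

* **Loop counting.** The 3p rule is operationalized as: exactly two paired
  nucleotides between the nearest upstream single-stranded nucleotide and
  the 3p 5′ end (p−1 and p−2 paired, p−3 single-stranded). The "0-nt" 5p
  variant — the position immediately 3′ of the 5p end is single-stranded —
  is then the k = 0 member of the same family. The off-by-one convention is
  not uniquely determined by the phrase "2 nt downstream of a bulge/loop";
  this reading is documented as the package's, not asserted as anyone
  else's.
* **3′/5′ counting as geometry.** For each tertiary model, the Euclidean
  distance from the C5′ atom of the first 3p nucleotide to the O3′ atom of
  the pre-miRNA 3′ end (D_3p_miRNA), and its 5p mirror; medians are taken
  over the model ensemble (the 50 lowest-energy models when more are
  supplied). Membership: |D − 59 Å| ≤ 1 Å, both constants configurable; the
  59 Å target mirrors the processing-center geometry of the Dicer complex
  (~58 Å pocket-to-active-site), which is documentation, not a fitted
  value. Medians (not per-model distances) are used throughout, including
  isoform comparisons.
* Atom-name dialects C5*/O3* are normalized to C5′/O3′ on PDB input.

# The synthetic-data generator

The generator defines the package's study conditions:

* **Hairpins**: perfect Watson–Crick stems with random loops; the benchmark
  cohort is 50 hairpins, 15-bp stems, 9-nt loops (39 nt — small-RNA scale).
* **Reads**: full-length, with per-position mutation probabilities
  `mod_rate_ss = 0.02` at unpaired and `mod_rate_ds = 0.002` at paired
  positions plus `background_rate = 0.002` (DMSO = background only), at
  2000× depth — a 10× contrast over a realistic MaP background at the
  recommended depth. Event types are drawn 70% mismatch / 15% 1-nt deletion
  / 15% 1-nt insertion; the rarer multi/complex classes emerge from event
  merging and are additionally exercised by hand-built reads in the tests.
* **Count tables**: condition B's proportions are condition A's scaled by
  2^effect and renormalized; counts are multinomial.
* **Helix models**: one tracked point per residue per strand on a cylinder
  (rise 2.81 Å, twist 32.7°, radius 9 Å, A-form-like; strand-2 phase offset
  150°, an arbitrary recorded constant). C5′ and O3′ are coincident per
  residue, so chord distances obey
  d(n) = √((n·rise)² + (2r·sin(n·twist/2))²) exactly — the closed-form
  oracle for the geometry code. Model ensembles are produced by isotropic
  Gaussian jitter (σ = 0.5 Å).

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: context-dependent modification
efficiency, base-composition bias of mutation types, correlated errors
within reads, alignment artifacts (the reads are born aligned), partial
reads, endogenous modifications (tested only via the masking path), and
real tertiary geometry (an ideal cylinder stands in for modeled ensembles).
Benchmarks on this generator measure the pipeline's correctness and
statistical behavior, not biological accuracy.

# Numerical and reproducibility choices

Problem sizes were chosen so the full suite and the acceptance script run
comfortably on one CPU: 50-transcript cohorts at 2000×, 4000-base QC
tables, 10⁶-read count tables, 180-profile clustering, 50-model ensembles,
and folding oracles at length ≤ 14 (where exhaustive enumeration is cheap).
Every stochastic routine takes an explicit seed; the pipeline derives
per-stage seeds from the config seed, stamps each output with the package
version, a hash of the analysis parameters (not the output path) and the
seed, and reruns byte-identically. Energy comparisons use 1e−6 tolerances
(floating summation order); rigid-motion invariance holds to 1e−9.

# Known limitations

* The folding model is reduced (no dangles/coaxial terms, approximate GU
  stacks); predicted structures are constraint-consistent MFE models, not
  reference-grade thermodynamics.
* Mutation rates are modeled per position, independent across positions; at
  very high modification rates, event merging makes observed per-position
  event rates sub-additive.
* The loop-counting operationalization and the complex-event labelling are
  declared conventions where the underlying definitions are ambiguous.
* Spliced (N-op) alignments are rejected — small-RNA references are
  unspliced by construction.
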