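---
title: "Structural descriptors for subcellular-location classification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural descriptors for subcellular-location classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structloc)
```

# The problem and the representation

Protein subcellular location correlates with 3D structure: membrane
proteins are helix-rich with hydrophobic surfaces, nuclear proteins carry
charged surface patches, and so on. `structloc` turns one protein chain —
an ordered list of residues with N/Cα/C coordinates — into several
fixed-length descriptor vectors and classifies them into four location
classes (nucleoplasm, plasma membrane, cytosol, mitochondria). Every
descriptor is a function of Cα geometry and residue identity only, and
every one is invariant to rigid motions of the structure, which the test
suite checks by applying random rotations and translations.

All distance units below are Ångström; all angles are degrees.

# Structure input

`read_pdb_structure()` parses ATOM records through bio3d and reduces them
to one residue table. Decisions a PDB file forces on us:

* **Multi-model files**: only the first model is used.
* **Chain choice**: when no chain is requested, the chain with the most
  Cα atoms is kept. This is a stand-in rule; curated benchmarks usually
  specify a chain per entry, and callers can.
* **Alternate locations** resolve to the highest occupancy, then first
  encountered.
* **Nonstandard residues** map to `X`: they keep their coordinates (so
  distance-based descriptors are unaffected) but are excluded from every
  composition.
* **Chain breaks**: consecutive residues whose Cα–Cα distance exceeds
  `max_link = 4.5` (the trans virtual bond is ≈ 3.8) or whose numbering
  jumps start a new segment. Dihedral angles and Gauss integrals never
  span a break; crystal structures are frequently fragments, so this
  matters in practice.

# The descriptors

## Contact matrix (1680)

All unordered Cα–Cα distances between standard residues are histogrammed
into 8 bins of 8 covering [0, 64); distances ≥ 64 are discarded rather
than clipped, since the binning is defined as ranging to 64. One
histogram per unordered amino-acid pair gives 8 × 210 = 1680 counts. The
210 pairs are ordered alphabetically by one-letter code with i ≤ j — an
arbitrary but fixed convention that makes outputs comparable across runs.
Because 1680 is large relative to typical sample sizes, the experiment
runner applies stepwise discriminant selection to this block per fold
(below).

## Dihedral-angle curves (30)

φ(i) uses C(i−1), N(i), Cα(i), C(i); ψ(i) uses N(i), Cα(i), C(i),
N(i+1); both are standard signed torsions in [−180, 180]. Each curve is
linearly resampled to length 64, mean-centered (the raw angle level
carries no information once secondary structure sets the offset, and
centering removes the constant), and summarized by

* the magnitudes of discrete-Fourier coefficients 1–8, and
* the 7 relative energies of a Haar wavelet pyramid (6 detail levels of
  a length-64 series plus the final approximation), normalized to sum 1.

That is 15 values per curve, 30 per protein. The exact 15-feature recipe
is a package choice: resampling makes chains of different length
comparable, the low-order Fourier magnitudes capture periodicity
(helices and strands differ sharply there), and relative wavelet
energies capture how variance distributes across scales. Both the
resampling length and the transform set are arguments of
`dihedral_features()`' internals and documented here rather than tuned.
Series shorter than 8 angles are zero-padded; empty series produce a
zero vector with a warning.

## Compact sub-structures and their frequencies

A 10 × 10 window slides over the Cα distance matrix at row/column
offsets that are multiples of 5; a window whose 100 entries average
below 15 is a compact sub-structure. Off-diagonal windows pair
discontiguous sequence stretches — tertiary contacts. Since the distance
matrix is symmetric, the mirrored window (cols, rows) duplicates
(rows, cols); we enumerate only row-offset ≤ col-offset. Each kept
window is represented by its 100 distances (row-major) plus the 20-dim
composition of the covered residues: 120 values.

The codebook is built by two-stage agglomerative clustering (average
linkage, Euclidean): first within each protein, cut at height
`local_t`; then on the pooled per-protein centroids, cut at `global_t`.
Two stages exist because the pooled set of raw sub-structures is far too
large to cluster directly on real data. The linkage and metric are
package choices; the defaults `local_t = 10`, `global_t = 20` (in
120-dim rep units) are starting points of a configurable grid, and the
codebook size — hence the frequency-descriptor length — is an outcome of
the data and thresholds, not a constant of the method. A protein's
descriptor is the proportion of its sub-structures assigned to each
global centroid (nearest Euclidean centroid, ties to the lowest index
for determinism); it sums to one whenever the protein has at least one
sub-structure.

## Surface chemistry (42)

A residue is *surface* when at least one of 12 equal solid-angle sectors
around its Cα contains no other Cα within `radius = 12`. The sectors
are the face cones of a regular dodecahedron (nearest-axis assignment).
Two choices need justification:

* **Sector frame.** A fixed laboratory frame would make the surface
  mask depend on the orientation of the deposited coordinates. We
  therefore anchor the sector axes to the principal axes of the Cα
  cloud, with signs oriented toward the farthest-from-centroid point
  and a right-handed third axis. The mask is then invariant under
  rotations and translations (tested), at the price of instability in
  the rare case of a nearly spherically symmetric cloud.
* **Neighbor radius.** 12 Å covers roughly two contact shells; smaller
  radii declare nearly everything surface, larger ones nearly nothing.
  The value is an argument (`surface_residues(p, radius = )`), and the
  descriptor varies smoothly with it.

The descriptor is the 20-dim surface composition α followed by the 22
property expectations f(i) = Σ_j α_j p_j(i). The default property table
combines published scales (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, Grantham polarity, net charge at pH 7, Zamyatnin
volumes, residue masses, isoelectric points, Chou–Fasman helix/sheet/
turn propensities, Zimmerman bulkiness) with explicitly defined
chargeability and indicator properties (aromatic, aliphatic, polar
uncharged, sulfur, hydroxyl, amide, positively/negatively chargeable,
small, β-branched), exactly 22 named columns. Any 20 × 22 table can be
supplied from a delimited file via `read_property_table()`; expectations
are bounded by the per-property min and max over amino acids, which the
tests assert.

## Gauss integrals (31)

The backbone's longest continuous segment is a polygonal space curve.
For every non-adjacent edge pair (a, b) the exact Gauss double integral
w(a, b) — the signed solid angle spanned by the two segments, evaluated
in closed form — measures their average signed crossing over all
projection directions. The descriptor family is:

1. the writhe Wr = Σ_{a<b} w(a, b) (component 1),
2. the average crossing number Σ |w| (component 2),
3. the order-2 integrals: sums of w(c₁)·w(c₂) over chord patterns
   (12)(34), (13)(24), (14)(23), each in the four signed/absolute factor
   combinations (12 values),
4. the 15 signed order-3 integrals, one per perfect matching of six
   ordered edge positions, and
5. fully-absolute variants of the sequential (12)(34)(56) and fully
   crossing (14)(25)(36) patterns (2 values),

for 31 in total. The canonical enumeration of the order-≤3 family used
in the structure-classification literature is not fully recoverable from
available descriptions, so this allocation is the package's documented
choice with the writhe pinned as component 1. Verification is two-fold:
the writhe is checked against an independent adaptive-quadrature double
integral (agreement ~1e-15), and the full family is checked for
rigid-motion invariance and the parity rule under reflection (components
with an odd number of signed factors flip sign, absolute components do
not). Computation is in C++: prefix-sum tables collapse the last chord,
making order-2 terms O(m²) and order-3 terms O(m⁴) with an O(1) inner
step for m edges; curves longer than 150 vertices are uniformly
subsampled first, a deliberate approximation that keeps long chains
tractable.

## Persistent homology (34)

Growing equal-radius balls on the Cα atoms and linking two residues when
their balls touch is exactly a Vietoris–Rips filtration on the pairwise
distances. We compute homology in dimensions 0–2 (components, rings,
cavities) up to `max_radius = 16` by boundary-matrix reduction over
GF(2) in C++ (simplices through dimension 3, filtration value = longest
edge; zero-persistence pairs dropped; the one essential component keeps
death ∞). The reduction is validated against an independent plain-R
oracle that enumerates simplices explicitly and computes Betti numbers
from boundary-matrix ranks, and against single-linkage `hclust` heights
for dimension 0.

The 34 statistics are, per dimension h ∈ {0, 1, 2}: bar count; birth
counts in four 4 Å bins; death counts in the same bins; minimum birth;
maximum death (infinite deaths capped at 16 before binning and maxima);
plus the total bar count — 3·(1+4+4+1+1)+1 = 34. The bin layout and the
16 Å cap are package choices (4 Å is the scale separating bonded from
packing contacts; beyond 16 Å little protein topology is born) and both
are arguments.

## Graph attention encoder (84)

Compact sub-structures (threshold 10 here, so that even loosely packed
chains yield nodes) become graph nodes, featurized by the 42-dim
composition + property-expectation layout computed on the covered
residues; nodes whose centroids are closer than 10 are connected. Three
attention layers of width 42 follow: layer scores
e_ij = LeakyReLU(u · [W h_i ‖ W h_j]) over each node's neighborhood
including a self-loop (so single-node graphs are well-defined), softmax
normalization (rows sum to 1, tested at every layer), and a rectifier on
the aggregated output. Mean and per-dimension max over nodes are
concatenated: 42 + 42 = 84, which fixes the layer width given the
target output size. Training attaches a linear softmax head and runs
full-batch Adam (default 300 epochs, learning rate 5e-3, analytic
backpropagation verified against numerical differentiation); after
training the head is discarded. Weights, the attention wiring, and the
schedule are package choices: only the layer count, the aggregation and
the output size are fixed by the descriptor contract. Inside
cross-validation the encoder is trained per fold on training rows only,
to keep the representation leakage-free even though it is label-trained.

# Selection, classifiers, fusion

**Stepwise discriminant analysis** (`stepwise_discriminant()`): forward
steps add the feature with the largest partial F
(F = (n−g−p)/(g−1) · (Λ_before/Λ_after − 1), Λ = det W / det T) when it
exceeds `f_enter = 3.84`; backward steps drop features whose
F-to-remove falls below `f_remove = 2.71`; classical screening defaults,
with a `max_features = 256` cap. Wilks' lambda is non-increasing along
forward steps (tested), constants can never enter, and ties break to the
lowest index so reruns are identical.

**Classifiers.** SVMs are RBF-kernel `e1071::svm` with pairwise-coupled
probability outputs; `c` and `g` come from an inner 5-fold grid search
(defaults 2^{−5..15} × 2^{−15..3}, steps of 2²). Random forests use
`randomForest` with the tree count grid {100, 300, 500, 1000} and class
vote fractions as scores. Folds are stratified by class: the benchmark
classes are imbalanced, and stratification stabilizes the smallest one;
a `stratified = FALSE` switch restores plain random folds. Fold sizes
differ by at most one. F1 is macro-averaged (unweighted over classes).

**Fusion.** Feature level: per-block standardization (training-fold
statistics only) followed by concatenation, or a multi-kernel SVM on
Σ w_k K_k with per-block RBF kernels and convex weights searched on a
simplex grid (step 0.01 for two blocks — fine enough to represent
weights such as 0.83/0.17 — and 0.05 for three) by inner-CV accuracy.
Decision level: unweighted score averaging, or weighting by each model's
training-fold CV accuracy; rows are renormalized to sum 1 in both. For
the precomputed-kernel SVM, probability-like scores are obtained by
aggregating the one-vs-one decision values per class and applying a
softmax; this choice (rather than a per-fold Platt calibration) is
documented because kernel-matrix models do not expose calibrated
probabilities reliably. `paired_score_test()` compares two models by a
two-sided paired t-test on their true-class scores, with the degenerate
zero-variance case returning p = 1.

All fold-dependent artifacts — codebooks, selections, scalers, encoder
weights, kernel weights — are fitted strictly on the training rows of
each fold. The tests assert this directly by perturbing validation rows
and checking the artifacts bit-for-bit.

# The synthetic generator

`make_segment()` builds backbones atom-by-atom from internal coordinates
(N–Cα 1.46, Cα–C 1.52, C–N 1.33; angles 111/116.2/121.7; ω = 180) with
ideal helix (−57, −47) and strand (−119, 113) dihedrals; coil draws
φ/ψ uniformly. `generate_dataset()` alternates structured segments with
short coil linkers, draws residue identities from a class-specific
multinomial, and redraws any chain with a Cα–Cα pair closer than 2.5 Å
(rejection with 100 retries). Everything is reproducible from one seed.

The four default class profiles are deliberately *strongly separated*:
helix-rich (85/5/10 helix/strand/coil), mixed (45/45/10), strand-rich
(5/85/10), and coil-rich (25/25/50), with disjoint composition biases
(charged, hydrophobic, polar, small residues upweighted 6×) and chain
lengths of 30–60 residues. These are the study conditions for the
recovery checks: with 30 proteins per class, a random forest on the best
single descriptor must beat twice chance, and fusing two descriptors
must not lose more than two accuracy points. The sizes keep the full
experiment around one to two minutes on one core; the methods scale to
real chains, where the Gauss order-3 terms and the Rips reduction
dominate runtime.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: side chains (surface detection on real
proteins would see different packing), realistic sequence correlations
beyond composition, structural noise and missing residues (handled by
the parser but not generated), domain architecture beyond one compact
chain, and any genuine link between structure and *biological* location.
Synthetic recovery demonstrates that the descriptors transmit planted
geometric and compositional signal through the full pipeline, not that
they attain any particular accuracy on curated benchmarks.

# Numerical choices and degenerate inputs

* Distances ≥ 64 in the contact histogram are discarded, not clipped.
* Dihedral series shorter than 8 are zero-padded; empty series give
  zero vectors with warnings.
* Sub-structure assignment ties break to the lowest centroid index;
  stepwise selection ties to the lowest feature index; score argmax ties
  to the first class in canonical order (nucleoplasm, plasma membrane,
  cytosol, mitochondria).
* Proteins with fewer than 10 residues have no sub-structures; fewer
  than 4 residues in the longest segment give a zero Gauss descriptor
  with a warning; fewer than 2 standard residues make the contact
  descriptor an error.
* The Rips reduction refuses complexes above 5e6 simplices rather than
  exhausting memory; lower `max_radius` for very large chains.
* The four-point torsion is invariant under reversing the chain
  direction and negated by mirror reflection; the tests encode these
  identities.
* Constant feature columns pass through standardization unscaled
  (divisor 1) so they cannot produce NaNs downstream.

# Known limitations

* The 22-property table is assembled from standard published scales;
  any particular historical 22-property set can be substituted via
  `read_property_table()` but numerical equality with unpublished
  tables is unattainable.
* The order-≤3 Gauss enumeration and the 34-slot barcode layout are
  documented package allocations; alternative allocations of the same
  ingredients would be equally valid and would change feature values
  but not dimensionality or invariances.
* `gat_forward()` on graphs with hundreds of nodes allocates dense
  n × n attention matrices; this is fine for sub-structure graphs but
  not for residue-level graphs.
* The multi-kernel weight search is a grid, not a solver; with strongly
  separable data many weights tie at the same inner accuracy and the
  first maximizer (lowest first-block weight) is returned.
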