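# structloc

Structural descriptors and classifiers for protein subcellular-location
prediction from 3D structure.

Protein location in the cell (nucleoplasm, plasma membrane, cytosol,
mitochondria) is usually predicted from sequence. `structloc` instead
represents a protein by handcrafted descriptors of its 3D backbone and
feeds them to standard classifiers, so that structural information can be
used on its own or fused with external sequence-based predictors.

## Descriptors

For a chain with Cα coordinates `x_1 … x_n` the package computes:

* **Contact matrix** (1680): counts of Cα–Cα distances per unordered
  amino-acid pair, in 8 distance bins of 8 Å covering [0, 64) Å —
  8 × 210 cells after removing symmetric duplicates.
* **Dihedral-angle curves** (30): the signed backbone torsions
  φ(i) = ∠(C(i−1), N(i), Cα(i), C(i)) and
  ψ(i) = ∠(N(i), Cα(i), C(i), N(i+1)); each curve is resampled to length
  64, mean-centered, and summarized by 8 Fourier magnitudes plus 7
  relative Haar wavelet-level energies.
* **Sub-structure frequency** (codebook size): 10 × 10 windows of the
  distance matrix at stride 5 with mean internal distance < 15 Å, each
  represented by its 100 distances + 20-dim amino-acid composition,
  clustered in two stages (per protein, then globally); a protein is the
  vector of its sub-structure proportions over the global centroids.
* **Surface chemistry** (42): a residue is a surface residue when at
  least one of 12 equal solid-angle sectors around its Cα (within 12 Å)
  contains no neighbor; the descriptor is the surface amino-acid
  composition α plus the 22 property expectations
  f(i) = Σ_j α_j · p_j(i).
* **Gauss integrals** (31): the writhe Wr = Σ_{a<b} w(a,b) of the Cα
  polygon, where w(a,b) is the exact Gauss double integral (signed
  solid angle) over edge pair (a,b); the average crossing number; and
  generalized integrals of chord-pattern order ≤ 3 in signed and
  absolute variants.
* **Persistent homology** (34): barcode statistics (counts, binned birth
  and death radii, extreme endpoints) of a Vietoris–Rips filtration on
  the Cα cloud up to 16 Å, homology dimensions 0–2.
* **Graph attention encoder** (84): compact sub-structures become graph
  nodes (42-dim composition + chemistry features, edges between
  centroids < 10 Å); three attention layers followed by mean‖max pooling
  give the representation, trained with a linear softmax head and Adam.

Classification uses RBF-kernel SVMs (probability outputs, grid-searched
`c`/`g`) and random forests (grid-searched tree count) under stratified
10-fold cross-validation, with stepwise discriminant analysis (Wilks'
lambda, partial-F) to shrink the contact descriptor. Descriptors and
external per-protein feature or score files can be fused at the feature
level (standardized concatenation, multi-kernel SVM over convex kernel
combinations) or the decision level (score voting, accuracy-weighted
voting), with a paired t-test on true-class scores to compare models.

A parametric generator builds synthetic backbones (ideal-geometry
helices, strands, coils with standard bond lengths and angles) under
four class profiles with distinct secondary-structure mixes and
composition biases, so the entire pipeline is testable offline.

## Worked example

```r
library(structloc)

ds <- generate_dataset(synth_spec(n_per_class = 30, seed = 7))
ex <- run_experiment(ds$structures, ds$labels,
                     descriptors = c("dihedral", "gauss", "chemical"),
                     model = "rf", fuse = c("vote", "concat"), seed = 7)
print(ex)
#> subcellular-location experiment (rf, 10-fold CV, n = 120)
#>   dihedral       accuracy 0.5583  macro-F1 0.5546
#>   gauss          accuracy 0.5500  macro-F1 0.5435
#>   chemical       accuracy 1.0000  macro-F1 1.0000
#>   fused(vote   ) accuracy 0.9583  macro-F1 0.9583
#>   fused(concat ) accuracy 1.0000  macro-F1 1.0000
```

Read: each line is the 10-fold cross-validated accuracy and macro-F1 of
one descriptor (or fusion) with a random forest on the 120 synthetic
proteins. Chance is 0.25. The dihedral and Gauss descriptors see only
backbone geometry, so they separate the four classes partially (the
profiles overlap in structure); the chemical descriptor sees the planted
composition bias and separates them fully; fusion tracks the best block.

Single structures work the same way (`read_pdb_structure("file.pdb")`
for real files — first model, maximum-Cα chain):

```r
p <- ds$structures[[1]]
print(p)
#> protein_structure 'nucleoplasm_001' chain A: 39 residues
head(gauss_integrals(p), 2)
#>    writhe       acn
#> -2.760451  6.649996
ph_features(persistent_homology(p))[c("h1_count", "h1_min_birth")]
#>     h1_count h1_min_birth
#>    25.000000     5.197507
```

The writhe (−2.76) is the signed self-crossing number of this mostly
helical backbone; the 25 H1 bars are the transient loops the growing-ball
filtration sees, the first appearing at radius 5.2 Å.

A command-line front end covers the batch workflow:

```sh
Rscript scripts/structloc-cli.R synth      --out data/ --n 30 --seed 1
Rscript scripts/structloc-cli.R extract    --pdb-dir data/ --out feats/
Rscript scripts/structloc-cli.R experiment --pdb-dir data/ \
        --labels data/labels.tsv --out report/
Rscript scripts/structloc-cli.R fuse --method vote \
        --blocks a_scores.tsv,b_scores.tsv --out fused.tsv
```

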