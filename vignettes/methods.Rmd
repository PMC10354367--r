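---
title: "Voxelized variant microenvironments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelized variant microenvironments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxmut)
```

## The problem and the model

A missense variant substitutes one amino acid in a protein. Whether the
substitution is pathogenic depends strongly on *where* it lands: the
physicochemical and evolutionary context of the residue in three
dimensions. voxmut encodes that context directly. For a variant mapped to
a crystal structure, the package:

1. extracts every heavy atom within 10 Å of the variant residue's Cα
   (the *microenvironment*),
2. computes per-atom feature values — element-indicator densities,
   partial charges, solvent accessibility, summed pairwise Coulomb and
   Lennard-Jones potentials, and residue-level conservation scores
   (PSSM profile, information content, wildtype/variant scores) spread
   onto each residue's atoms,
3. maps each feature channel onto a 20 × 20 × 20 grid of 1 Å voxels
   centered on the Cα, using a Gaussian kernel per atom,

   $$w_k(\mathbf r) = v_k \exp\!\left(-\frac{\lVert \mathbf r - \mathbf r_k\rVert^2}{2\sigma_k^2}\right),$$

   where $v_k$ is the atom's feature value, $\mathbf r_k$ its position
   and $\sigma_k$ its van der Waals radius, giving a
   (20, 20, 20, 31) tensor, and
4. classifies the tensor with a 3D convolutional network whose softmax
   head emits benign/pathogenic probabilities.

Training follows the protocol of the published framework: protein-level
cross-validation (no protein contributes variants to both training and
validation of a fold, guarding against type-1 circularity), balanced
benign/pathogenic subsets by down-sampling, five random-rotation
augmentations per grid (each treated as a training instance; at
prediction time the six per-grid probabilities are averaged into one
score), AdamW with cross-entropy loss, and Matthews correlation (MCC)
plus accuracy/TPR/FPR/AUC for evaluation.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| environment radius | 10 | Å | inclusive, measured from the variant Cα |
| grid size / voxel | 20 / 1 | voxels / Å | a 20 Å box; the grid-size experiment uses 15 |
| Gaussian width σ | per atom | Å | the atom's van der Waals radius |
| augmentations | 5 | — | uniform random rotations about the grid center |
| learning rate / weight decay | 0.001 / 0.005 | — | AdamW, full-scale protocol defaults |
| epochs / batch | 10 / 256 | — | full-scale protocol defaults |
| dropout | 0.5 | — | on both fully connected layers |
| SASA probe / points | 1.4 / 960 | Å / — | Shrake–Rupley, deterministic golden-spiral lattice |
| RSA burial threshold | 0.20 | — | Rost–Sander maxima; exposed strictly above |
| decision threshold | 0.5 | — | strict; ties are called benign |

## Design choices where the design was open

**Distance reference.** The neighborhood is measured from the variant
residue's Cα with an inclusive (≤) boundary, consistent with the grid
being centered on the Cα. Measuring from any atom of the residue is the
plausible alternative; it would grow environments by roughly one side
chain length.

**Nonbonded parameters.** The package ships a self-contained parameter
table (`inst/extdata/forcefield.tsv`): partial charges per residue/atom
name constructed so each residue's heavy-atom charges sum to its formal
charge, Lennard-Jones σ/ε and van der Waals radii per element, and
element-level fallbacks. Every numerical test of the energetics is
parameter-table-agnostic (closed forms and brute-force oracles), so
swapping in another table changes features but not correctness.
Electrostatics use K = 332.0636 kcal·Å·mol⁻¹·e⁻², no distance-dependent
dielectric, no shifting function. Combination rules: arithmetic mean for
σ, geometric mean for ε.

**Pairwise-potential contact set.** Per-atom Coulomb/Lennard-Jones sums
are computed for *all* environment atoms over non-bonded environment
pairs (atoms separated by up to two covalent bonds are excluded, with
bonds inferred geometrically from covalent radii + 0.4 Å). Restricting
the sums to the variant residue's atoms is the narrower alternative
reading; the superset is used because it is feature-complete for every
atom the grid sees.

**Site-score scoping.** Wildtype and variant PSSM scores are evaluated
at the variant position and placed only on the variant residue's atoms
(zero elsewhere); profile and information-content channels cover every
environment residue.

**SASA.** Computed on the full structure, not the environment, so burial
is physically meaningful; Shrake–Rupley with a deterministic
golden-spiral point set (no RNG), probe 1.4 Å. Residue-level RSA divides
summed atomic SASA by the embedded Rost–Sander maxima.

**Standardization.** Per-channel mean/sd are fit on training-fold voxels
only and applied unchanged to validation/test grids; standard deviations
are floored at 1e-8 so constant channels map to zero.

**Multi-structure variants.** When a variant maps to several structures
(at most three are admitted), per-structure averaged probabilities are
themselves averaged. The combination rule is configurable because the
source protocol does not state one.

**Pooling kernel.** The published layer table gives only "stride = 2"
for the pooling layer; kernel 2 is the unique choice reproducing the
printed 18 → 9 shape, and is fixed accordingly. Rectified-linear
activations follow each convolution, per the narrative description;
batch-norm layers sit where the table places them.

**B-factor normalization** is a per-structure z-score with the
population standard deviation, so a two-atom structure maps exactly to
−1/+1 and constant B-factors map to zero.

**Odds ratios** from 2 × 2 tables use the cross-product; any zero cell
triggers the Haldane–Anscombe +0.5 correction with an explicit flag.
MCC returns 0 whenever a denominator factor vanishes.

## The neural-network engine

No deep-learning framework is part of the package's dependency set; the
network is implemented in the package itself. Convolutions are im2col
matrix products against precomputed patch-index tables (all heavy
arithmetic is BLAS), with exact backpropagation (verified against
numerical gradients to ~1e-10 relative error in development), batch
normalization with running statistics, inverted dropout, and decoupled
weight decay (AdamW; weight matrices only). `shape_trace()` performs the
layer-shape arithmetic symbolically and is tested against shapes
observed by forwarding real tensors.

## What the synthetic generator emulates — and what it does not

`synth_structure()` builds idealized α-helical bundles (one chain per
helix, hexagonal packing) whose cores are genuinely buried — burial is
verified post hoc with the package's own SASA module, never assumed.
`synth_pssm()` writes PSI-BLAST-dialect profiles: conserved residues get
a sharply peaked row (wildtype column +7, others −3, ~4 bits);
non-conserved rows are near-uniform. `plant_variants()` samples variant
sites (half from rule-satisfying residues so labels are roughly
balanced), labels them by the planted rule *pathogenic ⇔ buried ∧
conserved* (RSA ≤ 0.20), flips labels at the configured noise rate, and
tags inheritance AD/AR round-robin. With zero noise an oracle
thresholding (RSA, conservation) recovers the labels exactly, so the
planted signal is fully present in feature space.

What the generator does **not** emulate: real folds and loop regions,
rotamer geometry, realistic PSSM column correlations (non-conserved
profile entries are independent noise), physically relaxed packing, and
the label structure of clinical data (where pathogenicity is not a
clean function of burial and conservation). Passing the end-to-end test
therefore shows that the pipeline can recover a known structural-plus-
evolutionary signal through featurization, voxelization and training —
it does not certify clinical performance.

## The desk-scale recovery experiment

The published experiments train on hundreds of thousands of augmented
grids; this package's end-to-end check runs on one CPU in minutes, so
the experiment is scaled down deliberately:

* 8 proteins × 30 variants, 10% label noise, 5 augmentations
  (≈1,440 grids);
* the 20 Å box is kept but discretized as 8³ voxels of 2.5 Å, which
  preserves the center-of-box signal while cutting compute ~30-fold
  versus 20³;
* a reduced network (batch-norm → input dropout 0.3 → conv 16 filters,
  kernel 2 → max-pool 2 → dense 32 → dropout 0.5 → softmax) trained
  ≤10 epochs with AdamW (learning rate 0.005, weight decay 0.05,
  batch 64), two protein-level folds.

The heavy regularization (input dropout, dropout 0.5, weight decay
0.05) is essential at this scale: the 20 random profile channels act as
protein-specific fingerprints that a small network happily memorizes,
and protein-level validation exposes exactly that failure. A run whose
final *training* loss never leaves chance level is re-initialized (at
most three times, seed shifted and learning rate halved — the standard
remedy when a high rate kills the rectified units early); the restart
decision looks only at training loss.

A useful calibration: with 10% label flips, even a classifier that
recovers the planted rule perfectly measures only ≈0.88 accuracy,
≈0.77 MCC and ≈0.89 AUC against the noisy labels (realized values for
the seed-1 bundle). Desk-scale results should be read against that
ceiling, not against 1.0: at these sample sizes the reduced network
typically reaches pooled MCC ≈ 0.5–0.56 and AUC ≈ 0.80–0.83, i.e.
roughly 70% of the attainable MCC and 93% of the attainable AUC, with
the protein-specific profile fingerprints the main generalization
obstacle.

## Numerical conventions and degenerate inputs

* Gaussian mapping is evaluated pointwise at voxel centers with no
  truncation radius; an optional cutoff would have to match the
  brute-force oracle within 1e-6 to be admissible.
* Empty environments, zero-distance atom pairs (clashes), missing PSSM
  rows, constant vectors in correlations, single-class strata and
  zero-cell contingency tables all produce typed errors or explicit
  flags rather than silent NaNs.
* All stochastic steps (rotations, splits, balancing, initialization,
  mini-batch shuffles) consume explicit seeds and restore the caller's
  RNG state.

## Known limitations

* mmCIF input, biological assemblies and homology mapping of variants
  onto related structures are out of scope; variant tables must arrive
  pre-mapped to the supplied PDB files.
* Secondary-structure channels (which require an external assignment
  tool) are not implemented; the normalized B-factor channel is
  available as an optional 32nd channel.
* The full 20³ × 31 network is implemented and shape-verified but is
  not trained in the test suite; training it to convergence is a
  GPU-scale exercise.
* PDB serials above 99999 wrap modulo 100000 on output (atom order and
  coordinates are preserved; serials are renumbered sequentially).
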