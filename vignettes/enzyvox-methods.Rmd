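---
title: "Voxel-based enzyme classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based enzyme classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzyvox)
```

## The problem

Enzymes are assigned to six top-level Enzyme Commission (EC) classes by the
chemistry they catalyze: oxidoreductases, transferases, hydrolases, lyases,
isomerases and ligases.  Protein structure is more conserved than sequence,
so a classifier that sees only the three-dimensional shape of a protein's
backbone is an attractive, alignment-free route to functional annotation.
`enzyvox` implements such a classifier: each structure becomes a binary
occupancy cube, and a small 3D convolutional network maps the cube to class
probabilities.

## The occupancy-grid representation

A structure enters the pipeline as its backbone point cloud: the N, C-alpha,
C and O atoms of every residue, all chains concatenated, in file order.
Side chains are deliberately ignored -- coarse shape, not atomic detail, is
the signal.  `voxelize()` then applies, in order:

1. **Interpolation.** Consecutive backbone atoms $A_i, A_{i+1}$ are joined
   by $p$ regularly spaced points $\big((p-k+1)A_i + kA_{i+1}\big)/(p+1)$,
   $k = 1..p$, in the original Angstrom coordinates.  At grid edge
   $l = 32$ consecutive atoms are closer than a voxel, so the default is
   $p = 0$; $p = 5$ and $p = 9$ are the defaults for $l = 64$ and
   $l = 96$, where holes would otherwise appear.
2. **Centering and uniform scaling.** The cloud is centered on the
   barycenter of the backbone atoms and scaled by the homothety ratio
   $\lambda = \lfloor l/2 - 1\rfloor / R_{max}$.  Every structure is scaled
   by the *same* ratio -- absolute molecular size stays visible to the
   classifier -- and everything outside the sphere of radius $R_{max}$
   (default 40 Angstroms, a compromise between capturing most enzymes
   whole and not wasting resolution) is clipped.
3. **PCA orientation.** Proteins have no canonical orientation, so the
   cloud is rotated into its principal-axis frame: axis 1 carries the
   largest variance.  Eigenvectors are sign-ambiguous; we fix each sign so
   that the third central moment of the projected coordinates is
   non-negative, falling back to a positive largest-magnitude loading when
   that moment is within $10^{-9}$ of zero.  The convention is
   deterministic but cannot remove mirror ambiguity entirely, which is why
   flip augmentation exists.
4. **Flips.** A flip code $(\delta_x, \delta_y, \delta_z) \in \{0,1\}^3$
   reflects the oriented cloud through the origin along the flagged axes.
   These are the only rigid maps that preserve the principal axes, hence
   the only augmentations that respect the orientation normalization.
5. **Voxelization.** Coordinates are shifted by $+l/2$ per axis and
   assigned to the nearest voxel index (rounding half away from zero);
   points assigned outside $[0, l-1]^3$ are dropped.  The voxel-vertex
   convention would equally support flooring; rounding is the default and
   flooring is available via `voxelizer_config(assignment = "floor")`.
   Because retained points satisfy $\|c\| \le \lfloor l/2 - 1\rfloor$,
   occupied voxels live in the interior $[1, l-2]^3$ and a one-voxel
   boundary margin is always empty.
6. **Outlier removal.** A single pass clears occupied voxels that have no
   occupied neighbor under the configured connectivity (default 26, the
   full 3x3x3 cube; 6 and 18 are available).  One pass only -- iterating
   to a fixed point could erode thin but legitimate structure.

Two readings of the backbone-atom set are defensible (three named atoms
versus four atoms per residue); we default to the four-atom set
{N, CA, C, O} and expose the choice through
`voxelizer_config(backbone_atoms = )`.  PCA uses every point in the cloud,
including interpolated ones, since they are part of the shape being
oriented.

## The classifier

The network is intentionally shallow, in the VoxNet tradition:

| layer | shape out | parameters |
|---|---|---|
| conv 32 filters $9^3$, stride 2, valid | $12^3 \times 32$ | 23,360 |
| conv 64 filters $5^3$, stride 1, valid | $8^3 \times 64$ | 256,064 |
| max-pool $2^3$, stride 2 | $4^3 \times 64$ | 0 |
| dense 128 | 128 | 524,416 |
| dense 6 + softmax | 6 | 774 |

for a total of 804,614 trainable parameters.  Valid (no-padding)
convolutions are the only scheme under which the flattened pool output is
$4^3 \cdot 64 = 4096$ and the total comes out at exactly that figure.
Leaky ReLU ($\alpha = 0.1$) follows each conv/dense layer; L2 of strength
0.001 penalizes kernels (not biases); dropout sits at three sites with
rates 0.2 / 0.3 / 0.4 (after conv1's activation, after the pool, after
dense1's activation) -- a VoxNet-like schedule, configurable in
`architecture_spec()`.

The loss is the class-weighted categorical cross-entropy
$L = -\sum_x \sum_i w_i\, \delta_{x,i} \log \hat p_{x,i}$.  Uniform
weighting sets all $w_i = 1$; adapted weighting sets
$w_i = \max_j c_j / c_i$ from the training-set class counts $c_i$, so the
largest class has weight exactly 1 and rare classes are up-weighted in
inverse proportion to their size.  Optimization is Adam (defaults
`learning_rate = 1e-3`, $\beta_1 = 0.9$, $\beta_2 = 0.999$, batch 32).
The forward and backward passes, including dropout and the optimizer, are
implemented in C++ (RcppArmadillo): convolutions are im2col gathers
followed by BLAS matrix products, which is what makes CPU-only training of
this architecture practical.  Mini-batch losses are averaged within the
batch for gradient scaling; the exported `weighted_cross_entropy()`
returns the summed form of the definition.

During training each pass re-shuffles the training set and draws, per
sample, three independent Bernoulli($p_{flip}$) flip indicators
(default $p_{flip} = 0.2$, under which $1 - 0.8^3 \approx 48.8\%$ of
samples receive at least one flip and higher flip counts are progressively
rarer).  Voxelized grids are cached per (structure, flip code), so each of
the at most 8 variants is computed once per run.

## Test-time decision fusion

`predict_final()` supports three strategies: classify the unflipped volume
(`none`); classify all flipped copies and fuse (`flips`); or fuse with
per-copy coefficients $1/(\delta_x + \delta_y + \delta_z + 1)$
(`weighted_flips`).  Fusion is either by summed probability or by
(weighted) majority vote over per-copy argmax classes.  The weighted
coefficient is well defined -- and maximal -- at the identity, so the
identity copy is included by default ($n = 8$ copies);
`include_identity = FALSE` gives the strict $2^3 - 1 = 7$ proper flips.
Ties are deterministic: probability fusion breaks toward the lowest class
index; majority voting breaks first by larger summed probability, then by
lowest index.

## Metrics

`confusion()` builds the 6x6 count matrix $C(i,j)$ (rows true, columns
predicted); accuracy is trace over total, per-class precision/recall are
the diagonal over column/row sums, F1 is their harmonic mean.  Macro
precision and recall are unweighted means over the six classes, and macro
F1 is the harmonic mean *of the macro precision and macro recall* -- the
mean-of-per-class-F1 alternative is available behind
`macro_metrics(cm, macro_f1_mode = "mean_f1")`.  On toy runs a class may
never be predicted, leaving its precision undefined: it is reported as 0
and flagged in the `"undefined"` attribute rather than silently dropped.

## The synthetic fixture generator

Full-scale training data would be a Protein Data Bank snapshot with tens
of thousands of enzymes; building and testing the artifact does not need
it.  `generate_trace()` emits backbone traces from six parametric shape
families -- straight rod, helix, ring, compact globule (a confined random
walk), ellipsoidal shell spiral, and a two-lobed dumbbell -- with four
atoms per residue at roughly 1.5 Angstrom spacing, isotropic Gaussian
noise (default 0.3 Angstroms), and per-family default radii between 12 and
30 Angstroms, i.e. small-protein-domain sizes well inside the 40 Angstrom
capture sphere.  `generate_labeled_dataset()` maps the families to EC
classes 1..6, jitters each sample's scale by up to 10% and writes minimal
fixed-column PDB files plus a labels CSV, so the identical I/O path is
exercised as for real data.

The families differ in coarse 3D shape and in absolute size -- exactly the
two signals the representation preserves -- so they are learnable by
design.  What they do *not* emulate: real backbone geometry (bond angles,
Ramachandran statistics), within-class structural diversity of real
enzymes, the heavy class imbalance of the PDB (available separately via
the `imbalance` argument), or any relationship between shape and actual
catalytic chemistry.  Passing the benchmark therefore demonstrates that
the pipeline is wired correctly end to end and that the network can
extract volumetric shape signal -- it says nothing about accuracy on real
enzymes, which requires the full-scale dataset and long training.

## Benchmark problem sizes

The package's standard scaled-down benchmark
(`synthetic_benchmark_split()`) uses 60 training and 30 test samples per
class (360/180 total), grid 32, 20 epochs, batch 32 -- sizes chosen so a
complete train-and-evaluate cycle runs in minutes on one CPU core while
leaving a wide margin over the 1/6 chance floor.  The full-scale result
the architecture was designed for (tens of thousands of PDB enzymes,
hundreds of epochs) is out of scope for this package's test surface.

## Numerical and degenerate-input choices

* Voxel assignment rounds half away from zero; inputs with coordinates on
  exact half-integer boundaries can land on either side under rotation
  and are avoided in tests.
* Rank-deficient point clouds (collinear/coplanar) get the available
  principal axes plus an arbitrary orthonormal completion, with a warning.
* Fewer than two points cannot be oriented and raise an error; a trace
  whose every point is clipped yields an empty grid with a warning.
* $\log$ clamping in the loss uses $\epsilon = 10^{-7}$ (with a warning at
  the R level; the C++ training path clamps at $10^{-12}$ merely to avoid
  `-Inf` in reported losses).
* Derived seeds: every stochastic component (weight init, shuffling, flip
  draws, dropout) draws from a stream seeded deterministically from the
  master seed, so whole runs are reproducible while per-epoch draws
  differ.
* `split_dataset()` is unstratified by default (proportions 64/16/20 via
  80/20 then 20% of training); a stratified option exists for small
  datasets where a class could otherwise miss a part entirely.

## Known limitations

* Single-channel binary occupancy only; no biochemical-property channels.
* Training grid size defaults to 32; the representation supports 64 and
  96, but the bundled architecture is fixed to a 32-cube input.
* One structure, one label: multi-label enzymes are rejected at load time.
* The grid cache written by `cmd_preprocess()` is an RDS container with
  the grid attribute set (grid size, capture radius, interpolation count,
  flip code) rather than an interchange format.
* PDB input only (first model, altloc blank/A); no mmCIF.
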