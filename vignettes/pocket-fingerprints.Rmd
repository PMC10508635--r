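---
title: "Structural pocket fingerprints for proteochemometric potency models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural pocket fingerprints for proteochemometric potency models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most kinase inhibitors in public bioactivity databases have been measured on
one or two kinases, yet the molecules themselves are rarely that selective.
Proteochemometric models fill in the missing cells of the compound-by-kinase
potency matrix by learning jointly from compound features and protein
features. The question this package addresses is what the protein feature
should be. Alongside the standard choices — a one-hot identity code,
physicochemical z-scales of the 85-residue ATP-pocket alignment, and k-mer
(ProtVec) sequence embeddings — it implements a structural fingerprint: the
flatten-layer activation of a 3D convolutional network trained to recognize
kinases from voxelized pocket structures.

## The model, stage by stage

### Voxelization

A prepared, pocket-aligned structure (PDB) is stripped of hydrogens and
waters and its heavy receptor atoms are mapped to 14 channels (four carbon
types split by aliphatic/aromatic and hydrophobic/polar character, four
nitrogen types by donor/acceptor character, two oxygen types, sulfur,
phosphorus, halogens, metals). Each atom deposits a truncated Gaussian on
its channel of a 48-voxel cubic grid with 0.5 Å spacing centered on the
non-hetero centroid:

* `exp(-2 d^2 / r^2)` for `d <= r` (`r` = per-type atomic radius, 1.5–2.1 Å),
* a quartic continuation `e^{-2}(0.96 u^4 - 3.92 u^2 + 3.96)` with `u = d/r`
  for `r < d <= 1.5 r` — continuous in value and slope at `r`, exactly zero
  at `1.5 r`,
* zero beyond.

The grid-origin convention places voxel `N/2` exactly at the grid center, so
an atom at the center attains density 1 at a voxel. Per-channel mass is
conserved under rotation to well below 2% for structures fully inside the
box, which the test suite asserts for random rotations.

Choices the input format does not pin down: spacing 0.5 Å (23.5 Å edge) is
the published default of the gridding libraries for this grid size; the
channel table ships as a TSV (`inst/extdata/atom_types_default.tsv`) and is
fully configurable; ligand (hetero) atoms are excluded — 14 channels is a
receptor-only layout; context flags are derived from residue/atom-name
heuristics of the standard amino acids, with element-level fallbacks.

### The convolutional classifier

The fixed architecture is AvgPool(2) – Conv(14→32, k3, pad 1) – ReLU –
Conv(32→32, k1) – ReLU – AvgPool – Conv(32→64, k3) – ReLU – Conv(64→64, k1)
– ReLU – AvgPool – Conv(64→128, k3) – ReLU – AvgPool – Conv(128→8, k3) –
Flatten – Linear(flatten → n classes). No activation sits between the final
convolution and the flatten, and none is applied there. For a cubic input
of edge `E` (divisible by 16) the flatten length is `8 (E/16)^3`; the
48-voxel default gives 216 — the length of the structural fingerprint. The
forward/backward passes are implemented natively (im2col + GEMM through
BLAS); a finite-difference check of every layer's gradient is part of the
development history and the optimizer follows the stated settings: SGD,
learning rate 0.01, momentum 0.9, cross-entropy loss.

Training choices left open by the architecture description and how they were
resolved:

* **Initialization.** Transfer learning from a pretrained general-purpose
  model is supported through `pretrained_weights_path` (all layers except
  the output head are loaded), but no weights ship with the package. The
  from-scratch default is He initialization followed by layer-sequential
  variance calibration on a seed batch (LSUV-style): sparse density grids
  are far from unit variance, and without the calibration the deep stack
  starts with vanishing activations and cannot move in the few hundred SGD
  steps a desk-scale corpus affords.
* **Rotation augmentation.** Each presentation can be voxelized under a
  fresh uniform rotation (unit-quaternion sampling). This is the default,
  matching how such networks are trained at corpus scale. At the package's
  fixture scale (96 structures, 50 epochs, a few hundred SGD steps) the
  augmented objective does not converge — rotation-robust features need
  orders of magnitude more presentations — so the bundled pipeline and test
  helpers train in the identity pose and the vignette's claims about
  augmentation are mechanistic (it runs, it reduces loss), not about final
  accuracy. Fingerprint extraction always uses the identity pose, making it
  bit-reproducible for fixed weights.
* **Batching and stopping.** Batch size 32 and 50 epochs are the defaults;
  the keep-best-test-loss checkpoint is returned. The fixture-scale runs
  use batch 4, because with ~90 training structures the number of SGD steps,
  not the epoch count, is what limits convergence.
* **Split.** The structure-level train/test split is stratified per label at
  90/10, seeded, mirroring the ratio of the corpus the method was designed
  on (3044/350).
* **Representative structures.** One fingerprint per kinase is extracted
  from the lexicographically smallest test-split structure id — a fixed,
  reproducible stand-in for an unstated choice.

### Compound standardization and fingerprints

Compounds arrive as SMILES and pass through RDKit (invoked as a bundled
Python helper behind the R surface): largest-organic-fragment salt
stripping, canonical tautomer, InChIKey, and a molecular-weight filter
keeping [180, 700] g/mol inclusive. InChIKey is the deduplication key, so
tautomer drawings of the same molecule collapse. Fingerprints are hashed
Morgan circular fingerprints, radius 2, 1024 bits, chirality ignored.
Tanimoto similarity of a test compound to its nearest training compound
feeds five similarity bins (`[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8),
[0.8,1.0]` — the top bin closed) used by the evaluation battery.

### Bioactivity curation

Raw records are disposed of by an ordered rule table: unknown protein →
reject; confidence below 7 (when the source carries a confidence score) →
reject; type outside {IC50, Ki, Kd, Potency, %inhibition, %activity} →
reject; missing value → reject; concentration types in nM with relation `=`
convert to pActivity `9 - log10(nM)`; relation `>=` at exactly 10,000 nM
becomes 5.0; relation `<` is censored and removed; other relations are
removed; %inhibition below 10 and %activity above 90 (both measured at
10,000 nM) become 5.0 and other percentage records are removed. Every
rejection carries a machine-readable reason and the counts always reconcile
with the input. After key resolution, exact (compound, protein, value)
duplicates across sources count once and repeated measurements collapse to
their median (even counts: mean of the middle two).

Edge decisions: `>=` at concentrations other than 10,000 nM and units other
than nM are rejected (the rule table names only the nM cases); `Potency` is
treated as a nanomolar concentration; the 10%/90% percentage boundaries are
strict.

### Splits, models, metrics

The **sparse split** must satisfy two constraints that a plain stratified
split cannot jointly guarantee: ~30% of every kinase's measurements in
test, and compound disjointness (a compound's measurements never straddle
the two sides). A seeded greedy pass assigns whole compounds to the test
side while their kinases have unmet quota, a repair pass guarantees every
kinase appears on both sides, and the achieved per-kinase fractions are
reported (on the default fixture they land within [0.25, 0.35]). The
**dense split** is deterministic: compounds measured on at least
`min_kinases_dense` kinases (60 for the 69-kinase corpus; the full panel
for the 8-class fixture) form the chemogenomic test set.

Six random forests (100 trees, remaining settings at the library defaults,
seeded; `ranger` is the engine) share the 1024-bit Morgan block and differ
in the protein block: none / one-hot / whole-sequence z-scales (5) /
per-residue z-scales (425) / ProtVec (100) / structural fingerprint (216).
The metric battery per model and split: RMSE, R², RMSE per Tanimoto bin,
error-band fractions (|error| in [0,0.5], (0.5,1], (1,1.5], (1.5,∞) — an
error of exactly 0.5 counts in the first band), a confusion battery at the
potency threshold 7.0 (positive means pActivity ≥ 7.0) overall, per kinase
and per compound with TPR/FPR/balanced accuracy/F1, and the per-kinase
median-baseline control (predicting every test pair with the kinase's
training median). Skewness is the bias-corrected sample estimator G1 (the
plain population-moment estimator is also exposed) and kurtosis is
bias-corrected Fisher excess kurtosis.

## What the synthetic fixtures emulate — and what they do not

The generator reproduces the statistical shape of a curated kinase corpus
at desk scale: 8 classes × 12 conformers sharing a scaffold cloud with
class-specific polar-atom motifs; 85-residue sequences sharing a consensus
with class-informative positions and a couple of alignment gaps; 1,000
unique, valid, weight-window compounds assembled from a fragment grammar so
that chemical series exist; and a bioactivity table whose non-panel
compounds are measured on one class 80% of the time while 30 panel
compounds cover every class — with ~5% extra censored/percentage/low-
confidence records to exercise every curation rule. The latent pharmacology
links the two sides: `pActivity = 5 + softplus(6⟨class, compound⟩ - 1.5)`
plus 0.3 log units of Gaussian noise, clipped to [4, 10]. The gain spreads
actives across the threshold and the shift puts the modal potency at the
inactive level with a right tail (positive skew), which is also why the
dense panel is inactive-dominated. Sparse-block target selection is
affinity-biased — compounds are measured on the kinases they were made for —
which is what separates the sparse and dense distributions in real data.

Passing tests on these fixtures show that every stage implements its
contract and that the benchmark reproduces the qualitative ordering
(protein-aware models beat the compound-only model on the dense panel; the
median baseline beats the compound-only model there too; structural
fingerprints cluster by class). They do not show chemically realistic
structure–activity relationships, docking-quality geometry, or the
published corpus-scale error figures, which require the real structure and
bioactivity corpora.

## Problem sizes and numerical choices

The bundled pipeline (also `scripts/acceptance.R`) runs the generator
defaults: 96 structures voxelized at 14×48³, a 50-epoch identity-pose CNN
at batch 4, 1,000 compounds, ~1,500 curated cells, and six forests on two
splits — about a quarter hour on one CPU. The test suite trains a smaller
16-voxel network for behavioural tests and a 15-epoch full-size network for
fingerprint tests. Other numerics: softmax is computed with max-shift
stabilization; the voxel kernel is cut exactly at `1.5 r`; deduplication
and representative-structure ties break lexicographically; the even-count
median is the mean of the middle two; groups lacking positives (or
negatives) report the affected classification rate as missing rather than
zero.

## Known limitations

* The structural fingerprint is only as good as the classifier behind it;
  at fixture scale the network separates the synthetic classes, but no
  claim transfers to real kinases without the real corpus.
* Rotation-augmented training is implemented and tested as mechanism, but
  desk-scale step budgets cannot converge under it (see above).
* Structure preparation (protonation, side-chain completion) is out of
  scope — inputs are assumed prepared.
* The Morgan/standardization stage requires the Python RDKit available on
  the PATH (bundled helper script); no R-native reimplementation is
  attempted.
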