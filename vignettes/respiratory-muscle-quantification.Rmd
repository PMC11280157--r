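---
title: "Quantifying respiratory muscles on thoracic CT with a three-stage Attention U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory muscles on thoracic CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(respmuscle)
```

## The problem

Respiratory function declines in diseases such as COPD, asthma and
pulmonary fibrosis, and the accessory respiratory muscles of the chest
wall — the pectoralis group ventrally, the erector spinae group
dorsally, and the intercostal muscles between the ribs — are both
effectors and markers of that decline. Single-slice muscle area at a
reference vertebral level is the traditional CT surrogate for muscle
mass, but it ignores the three-dimensional heterogeneity of the muscle.
This package implements a fully volumetric alternative: segment the
muscles on every axial slice of a thoracic CT with a neural network,
then quantify per-muscle **volume** (cc) and **density** (mean HU,
lower = fattier muscle) and relate them to pulmonary function test (PFT)
parameters by Spearman rank correlation.

Clinical CT cohorts of this kind are access-restricted, so the package
ships a synthetic thoracic **phantom generator** that reproduces the
structural assumptions the pipeline relies on. Everything — training,
inference, quantification, correlation — runs end to end on phantoms on
one CPU.

## The three-stage pipeline

1. **Muscle-tissue segmentation** — a binary Attention U-Net trained
   with Dice loss on three-channel windowed inputs.
2. **Respiratory-muscle segmentation** — the stage-1 network fine-tuned
   on respiratory-muscle masks with the first three encoder levels
   frozen (`freeze_encoder`), preserving the low-level features learned
   at stage 1. When unlabeled subjects are available, an
   active-learning loop (`run_active_learning`) predicts masks for a
   batch of them, passes the predictions through a refinement callback
   (the stand-in for expert correction), appends the accepted masks to
   the pool and retrains *from scratch* on the grown pool, repeating
   until the unlabeled pool is exhausted.
3. **Respiratory-muscle classification** — a softmax-head network of
   the same architecture assigns each segmented pixel to pectoralis (1),
   erector spinae (2) or intercostal (3), trained with generalized Dice
   loss.

At inference, `predict_subject()` chains the stages: binary
segmentation, connected-component noise filtering, classification of
the cleaned mask, and restriction of the class labels to the binary
mask.

## Network inputs

CT attenuation is an absolute scale (HU), so the inputs are fixed
linear windows, not per-image normalizations (`hu_window`):

* segmentation input — channel 1: full clinical range (−1024, 3071);
  channel 2: the muscle/fat band (−250, 150); channel 3: the band
  *below* muscle and fat (−1024, −250).
* classification input — channel 1: the binary respiratory-muscle mask;
  channel 2: the muscle/fat band; channel 3: the full range.

The upper bound of the third segmentation channel is taken as −250 HU:
a window "below the muscle/fat range" that reached up to +250 HU would
subsume the muscle/fat band itself and carry no complementary
information, so the signless rendering of that bound is treated as a
typo. Window bounds are configurable via YAML (`read_window_config`).

Augmentation (`augment`) applies a horizontal flip (p = 0.5) and an
in-plane rotation drawn from ±10° (p = 0.5) jointly to image and label
— bilinear interpolation for image channels, nearest neighbour for
labels, deterministic under a seed. The rotation range is deliberately
small so the transform does not alter the anatomy's chirality-free
features; the probabilities and range are package defaults since only
the transform types are externally specified.

## The network

`build_aunet()` constructs a U-shaped encoder–decoder with additive
attention gates on the skip connections. Each level is two 3×3
convolutions, each followed by batch normalization and ReLU; 2×2
max-pooling halves the resolution between encoder levels, and the
decoder mirrors this with bilinear upsampling followed by a 1×1 channel
projection. The attention gate combines the upsampled decoder signal
*g* and the encoder skip features *x* through learned 1×1 projections,
ReLU, a scalar 1×1 projection and a logistic squashing; the resulting
per-pixel coefficient multiplicatively reweights *x* before
concatenation. Channel width doubles per level. The binary head is a
1×1 convolution with a sigmoid; the multiclass head produces four maps
through a softmax.

The clinical-scale configuration is six encoder/decoder levels; the
width of the first level (`base_channels`) defaults to 32 for full runs
and 8 for phantom-scale instances, values chosen by us — the source
architecture specifies depth but not widths. The forward and backward
passes are implemented in the package itself (im2col + GEMM compiled
kernels orchestrated from R) with mini-batch Adam; the backward pass is
verified against finite differences in the test suite, which is the
strongest available correctness oracle for hand-derived gradients.

"Freezing the first three layers of the encoder" is implemented as the
first three *resolution levels*, the standard reading in a U-Net
context; frozen groups are skipped by the optimizer, so their
parameters are bitwise unchanged after any number of steps.

## Losses, schedule and evaluation

* Dice loss `1 − (2Σpt + s)/(Σp + Σt + s)` with smoothing `s = 1`
  during training; evaluation metrics use `s = 0`.
* Generalized Dice with squared-inverse class-volume weights
  `w_c = 1/(Σt_c + 1e-6)²`, which keeps small classes (the thin
  intercostal arcs) from being drowned out by the background.
* Adam, initial learning rate 1e-4, epochs 100/batch 8 for the tissue
  stage and epochs 50/batch 4 for the two respiratory stages (the
  clinical-scale schedule, kept as `stage_config` defaults); when the
  training loss fails to improve its running best (tolerance 1e-8,
  "improvement" being a strict decrease) for three consecutive epochs,
  the learning rate is multiplied by 0.30 ("reduced by 70%"), and again
  for every further full three-epoch stall.
* No early stopping: the epoch count is fixed, and when held-out data
  are supplied the best-epoch checkpoint by held-out (generalized) Dice
  is returned, filling the unspecified checkpoint-selection rule.
* Per-class precision/recall/F1/Dice (`classification_metrics`) are
  computed per volume and averaged unweighted across volumes; the
  aggregation order behind the reference cohort numbers is not
  recoverable from them (their printed F1 is not the harmonic mean of
  their printed precision and recall), so this convention is a declared
  choice. A class absent from both prediction and truth is vacuously
  perfect and reported as 1 with a warning rather than NaN.

## Post-processing

`remove_small_components()` deletes foreground components smaller than
`min_size_px` (default 10 at 512×512; the clinical pipeline filters
"components below a certain size" without stating the size),
slice-wise, 8-connected by default, 4-connectivity available.
Components exactly at the threshold survive. `resolve_class_priority()`
merges per-class binary masks under the total order pectoralis >
erector spinae > intercostal: the stated rule is that overlaps
involving the intercostal muscles yield to the other two; the
pectoralis/erector-spinae case is anatomically near-impossible and is
covered by the total order purely for determinism. Binary score maps
threshold at 0.5 with ties to foreground; multiclass argmax ties go to
the lowest class index.

## Quantification and correlation

Volume is voxel count × voxel size (row spacing × col spacing × slice
thickness / 1000, in cc); density is the plain mean of the *clamped,
unwindowed* HU over the class's voxels (no HU-range exclusion inside
the mask). Whole-muscle volume is the exact sum of the three class
volumes; whole-muscle density is the voxel-count-weighted mean of class
densities, the physically meaningful average. Cohort tables use the
sample SD (n − 1), with SD = 0 declared for n = 1 groups; age decades
follow the clinical cohort's 40–80 range with flagged open-ended bins outside
it.

CT–PFT pairing takes, per subject, the PFT record nearest the CT date
within ±90 days ("within three months"; calendar-month arithmetic is
ill-defined, so a fixed 90-day window is used and is configurable). One
CT per subject is required; duplicates are an error rather than a
silent resolution. `spearman_rho` is the Pearson correlation of
midranks; missing values are removed listwise per correlation cell,
maximizing each cell's n. P-values are not computed.

## The phantom

Each axial slice is a fat-density body ellipse (−100 HU) on air, with
two lung ellipses (−800 HU), a vertebral body and a thin rib ring
(+700 HU), and the three muscle compartments: paired ventral pectoralis
ellipses, paired dorsal paraspinal erector spinae ellipses, and thin
lateral intercostal arcs just inside the rib ring. Generating HU values
are constant per class (48 / 46 / 31 HU — inside the muscle/fat window
and ordered like real muscle densities, with the intercostals leaner),
plus optional Gaussian noise (default SD 8 HU; muscle voxels are kept
inside the window after noising so the invariant the pipeline assumes
holds with probability one). The default grid is 64×64×12 at
0.7×0.7×3 mm: coarse enough that a depth-4, 8-channel network trains in
minutes on one CPU, fine enough that every compartment is several
pixels across (the intercostal arcs are deliberately the hardest
structure at ~2 px).

Per-subject size jitter (log-normal, σ = 0.08), an age-related decline
(−0.6%/year from age 40) and a sex factor (male ≈ 1.28× female) drive
true-volume variation, qualitatively mirroring the reference
age/sex-stratified volume distributions. Synthetic PFT values are
affine in total muscle volume with additive Gaussian noise *on the
volume scale*; for a target Spearman ρ the noise SD is calibrated from
the realized cohort volume spread via the bivariate-normal relation
r = 2 sin(πρ/6), noise_sd = sd(V)·√(1/r² − 1). With zero noise the link
is strictly monotone and the rank correlation is exactly 1.

What the phantom does *not* emulate: scanner physics (beam hardening,
dose, kernels), anatomical variability beyond affine size changes,
partial-volume mixing at boundaries, and pathology. Passing phantom
tests therefore demonstrates that the pipeline's mechanics — windowing,
optimization, freezing, post-processing, quantification, pairing,
correlation — are correct, not that clinical-grade accuracy would be
achieved on hospital data.

## Scaled-down study sizes

The clinical-scale training runs (~600k images, 100/50 epochs, GPU hardware)
are out of scope; phantom-scale runs use deliberately chosen smaller
problem sizes, stated here as the package's own experimental design:

* end-to-end recovery: 80 subjects at 64×64×12 split 60/20 at subject
  level; depth 4, base width 8;
* binary stages: 2–4 epochs at learning rate 1e-3, batch 8;
* classification: 8 epochs at 2e-3, batch 8 — the thin intercostal
  arcs are learned in a characteristic late transition, and the higher
  rate moves that transition to roughly epoch 4;
* augmentation is disabled in these phantom runs: the cohort's size
  jitter already provides geometric variation, and nearest-neighbour
  label rotation measurably erodes 2-px-wide arc labels at this grid;
* correlation recovery: 300 subjects at target ρ = 0.8 (sampling error
  ≈ 0.06 at that n).

The learning rate is scaled up an order of magnitude relative to the
clinical schedule because the epoch budget is scaled down two orders;
the stage defaults in `stage_config()` keep the clinical-scale values.

## Numerical choices and degenerate inputs

* HU are clamped to \[−1024, 3071\] on every ingest path; clamping is
  idempotent.
* Dice of two empty masks is 1 (agreement on emptiness); density of an
  empty class is NA with a warning; Spearman of a constant vector is NA
  with a warning.
* Batch-norm uses ε = 1e-5 and momentum 0.1 with running statistics for
  evaluation mode, so inference is deterministic for fixed parameters.
* Subject-level splitting rounds the test fraction to the nearest
  integer, train takes the remainder; splits are seeded and slices of
  one subject never straddle the split.
* DICOM series are ordered by the z-component of ImagePositionPatient
  with InstanceNumber as tie-break; mixed in-plane geometry within a
  series is a hard error, as is missing spacing metadata.

## Known limitations

* The DICOM reader handles uncompressed little-endian single-frame CT
  slices — enough for the fixtures and typical exports, not a general
  DICOM implementation.
* Training is single-threaded apart from BLAS; clinical-scale
  (512×512, depth 6, width 32) training is functional but not fast.
* The phantom's PFT coupling is a one-factor monotone model; it cannot
  emulate parameter-specific physiology, only rank-correlation
  structure.
* Only axial geometry is supported; no resampling or reformatting is
  performed.
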