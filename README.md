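# respmuscle

Segmentation, classification and quantification of the accessory
respiratory muscles — pectoralis, erector spinae and intercostal groups —
on thoracic CT, with downstream correlation of the derived imaging
biomarkers against pulmonary function tests (PFTs).

## Who this is for

Researchers in body-composition and respiratory imaging who want a fully
volumetric alternative to single-slice muscle-area surrogates: instead of
measuring muscle area on one reference slice, segment the muscles on every
axial slice, and compute per-muscle **volume**

&nbsp;&nbsp;&nbsp;&nbsp;V = n·sᵣ·s꜀·t / 1000 (cc)

(voxel count × in-plane spacings × slice thickness) and **density**, the
mean Hounsfield unit over the muscle's voxels (lower HU = fattier,
lower-quality muscle). Volumes and densities are then rank-correlated
(Spearman ρ, Pearson correlation of midranks) with PFT parameters (FVC,
IC, VC, FEV1, TLC, FEV6, DLCO) paired to the CT within ±90 days.

## The method

Three networks share one architecture, an **Attention U-Net**: a U-shaped
encoder–decoder (two 3×3 conv + batch-norm + ReLU per level, max-pool
down, bilinear-up + 1×1 projection, channel width doubling per level)
whose skip connections pass through additive attention gates
α = σ(ψᵀ ReLU(W_g g + W_x x)) that reweight the encoder features x with
the decoder's gating signal g. The stages:

1. **Muscle-tissue segmentation** — binary sigmoid head, Dice loss, on
   3-channel HU-windowed inputs: full range (−1024, 3071), muscle/fat band
   (−250, 150), and the band below muscle/fat (−1024, −250).
2. **Respiratory-muscle segmentation** — stage 1 fine-tuned with the first
   three encoder levels frozen; optionally grown by an active-learning
   loop over unlabeled subjects with a mask-refinement callback.
3. **Respiratory-muscle classification** — softmax head over
   {background, pectoralis, erector spinae, intercostal}, generalized Dice
   loss with squared-inverse class-volume weights.

Training uses Adam with a plateau rule (learning rate × 0.30 after three
epochs without improvement). Predicted masks are cleaned by slice-wise
connected-component filtering and merged under the anatomical priority
pectoralis > erector spinae > intercostal.

The network, its backward pass and the optimizer are implemented in the
package itself (compiled im2col/GEMM kernels + R orchestration) and the
gradients are tested against finite differences.

Because the clinical cohorts behind this design are IRB-restricted, the
package includes a synthetic thoracic **phantom generator**
(`phantom_spec()`, `generate_cohort()`) producing CT volumes with
fat/lung/bone context, exact ground-truth three-class masks, age/sex-
driven volume variation, and PFT records monotonically coupled to true
muscle volume at a calibrated target rank correlation. Every claim the
package makes is testable against these phantoms.

## Worked example

```r
library(respmuscle)

spec <- phantom_spec(noise_sd_hu = 0)        # noise-free phantom
sub  <- generate_subject(spec, 2024)
print(sub$ct)
m <- muscle_metrics(sub$mask, sub$ct)
print(m)

coh <- generate_cohort(phantom_spec(), 120, seed = 9)
spearman_rho(coh$pft_df$FVC, coh$subjects_df$true_volume_cc)
```

prints

```
<ct_volume> subject P002024: 12 slice(s) of 64x64
  spacing 0.700 x 0.700 mm, thickness 3.00 mm, HU in [-1000, 700]
<muscle_metrics> subject P002024
  pectoralis          1.75 cc    48.00 HU
  erector_spinae      1.72 cc    46.00 HU
  intercostal         1.65 cc    31.00 HU
  whole_muscle        5.11 cc    41.85 HU
FVC ~ total muscle volume Spearman rho over 120 phantoms: 0.757
```

The densities are exactly the phantom's generating HU values (48/46/31,
noise-free), the whole-muscle volume is the exact sum of the three class
volumes, the whole-muscle density is their voxel-weighted mean, and the
recovered rank correlation sits near the generator's 0.8 target (the
link noise is calibrated via r = 2·sin(πρ/6)). To train and evaluate the
full pipeline on phantoms, write a YAML config and call
`run_pipeline("cfg.yaml")` or use the `run-all` CLI subcommand; artifacts
(checkpoints, metrics.csv, cohort summaries, correlation table, JSON log)
land in the configured output directory.

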