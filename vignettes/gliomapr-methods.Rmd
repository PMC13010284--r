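---
title: "Synthesising methionine-PET-like tumor maps from MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesising methionine-PET-like tumor maps from MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Glioblastoma infiltrates well beyond its gadolinium-enhancing core. The
non-contrast-enhancing tumor (nCET) is radiologically confusable with
vasogenic edema on T2-weighted MRI, yet it matters for surgical and
radiation planning. Amino-acid PET (¹¹C-methionine) maps tumor cell
density well enough to delineate nCET, but is expensive and scarce.
`gliomapr` implements a pipeline that learns to translate routine
contrast-enhanced MRI into a methionine-PET-like tumor-to-normal-ratio
map (a "gliomap") using a compact conditional GAN, together with the
bespoke intensity normalizations the approach depends on and the full
evaluation battery used to judge the result.

Because no patient cohort ships with the package, a synthetic phantom
module generates cohorts with a known latent cell-density ground truth;
every downstream stage is exercised and tested against it.

## Pipeline stages

### Mode-anchored MRI normalization

Multi-institutional MRI has arbitrary per-scanner intensity scales. For
each sequence (T1W, T2W, T1Gd) the package computes the 256-bin histogram
of brain-mask voxel intensities, takes the mode-bin center, and maps every
voxel of the full volume to

    v_norm = min(v * 75 / mode, 255)

so the dominant brain tissue sits at 75 on a 0–255 dynamic range without
observing any other subject. Values stay continuous; quantization to 8-bit
integers happens once, at pair export. Design choices the formula leaves
open and how we fixed them:

* **Bin range.** Bins span `[min, max]` of brain-mask intensities with
  equal widths. This keeps the procedure parameter-free and exactly
  scale-equivariant: scaling a volume by any positive gain scales the bin
  edges and the mode identically, so the normalized output is unchanged —
  the property that removes inter-institution gain, and a tested
  invariant.
* **Ties** break toward the lower-intensity bin (determinism).
* **Degenerate input.** A constant in-mask volume has a single-value
  histogram; its mode is that constant. A non-positive mode is an error
  since the division is undefined.
* **Background** voxels outside the head are scaled like everything else
  (they are near zero anyway); the normalization is deliberately applied
  to the non-skull-stripped volume.

### z-score contrast enhancement (zCE)

Subtracting T1W from T1Gd only weakly exposes subtle blood-brain-barrier
disruption. Instead, per subject, the package fits one ordinary least
squares line of normalized T1Gd on normalized T1W over brain-mask voxels —
the subject's no-enhancement relation — and expresses every voxel's
vertical distance from that line in units of the global residual SD:

    z(v) = (T1Gd_n(v) - a * T1W_n(v) - b) / sd(residuals)

The 8-bit encoding is `clip(z * 51, 0, 255)` (z = 5 saturates). Choices:

* One **global fit per subject**; a per-voxel residual SD is undefined
  with one observation per voxel, and a single SD is what makes the map a
  z-score image.
* The residual SD uses the **population (divide-by-n) denominator**, so
  brain-mask z-scores have mean 0 and SD exactly 1 by construction — a
  tested invariant at tolerance 1e-6.
* **Negative z encodes to 0.** The 8-bit image carries no sign;
  hypo-enhancement is not the object of the map. This is lossy and
  documented as such.
* The fit uses brain voxels only but the map is evaluated on the full
  grid; enhancing voxels are **not excluded** from the fit (with ~1% of
  brain voxels enhancing, their leverage on the line is small).

### PET tumor-to-normal normalization

PET SUV depends on injected dose and scanner protocol. Dividing the
volume by the mean SUV of a cerebellum reference mask yields a
tumor-to-normal (T/N) ratio invariant to global rescaling; the mean T/N
over the reference region is exactly 1. The 8-bit target encoding is
`clip(T/N * 51, 0, 255)`; decoding divides by 51, and voxels at 255 are
flagged saturated because their true T/N is only known to be at least 5.
Registration of an atlas cerebellum label to subject space is external
tooling; the mask is an input here (the phantom supplies it).

### Dataset assembly

One training pair per axial slice whose brain-mask coverage reaches
`min_brain_fraction` (default 0.05; the slice-inclusion rule is a free
parameter of the method). The source packs normalized T1W, T2W and
encoded zCE into R, G, B; the target is the encoded T/N slice. Slices are
center-cropped or zero-padded to a square power-of-two size (64 px at
desk scale). Horizontal mirroring doubles the training partition exactly;
the test partition is never augmented. Splits are by subject, never by
slice, so no subject leaks across partitions. When the pipeline caps the
training set (`max_train_pairs`), it takes a seeded uniform subsample of
slices before mirroring, so every kept slice trains together with its
mirrored copy; the held-out monitor is an evenly spaced selection of test
slices, which keeps it representative of whole-brain coverage.

### The conditional translator

A pix2pix-style conditional GAN: U-Net generator (4×4 stride-2
convolutions halving resolution to 2×2, mirrored transposed convolutions
with skip connections, sigmoid head scaled to [0, 255]) against a 70×70
receptive-field PatchGAN discriminator, trained with the adversarial
objective plus λ·L1 (λ = 100), Adam (lr 2e-4, β₁ = 0.5, constant for the
first half of training, then decayed linearly to zero), per-sample
channel normalization in every block except the first encoder and
discriminator layers, the innermost encoder layer and the output heads —
the published defaults at reduced scale. Omitting the normalization
layers destabilises training badly (the discriminator saturates and the
generator collapses to a dark constant), which is why they are not
optional. Decoder dropout (0.5 in the three innermost up-blocks, the
published full-scale default) is implemented behind `dropout`; it is on
in the `full` preset but off in `desk`, where the extra stochasticity
measurably hurts held-out accuracy at ~100 training slices. The networks
and backpropagation are implemented directly on im2col convolution
kernels (C++/Armadillo); gradients were verified against central finite
differences to ~1e-8 relative error.

Generated maps are masked to the brain by default
(`generate_gliomap(mask_to_brain = TRUE)`): a tumor-to-normal ratio is
undefined in air, and convolution border artifacts outside the head
would otherwise masquerade as lesions in threshold analyses.

Two presets: `desk` (64 px, 16 base channels, 10 epochs) trains in
minutes on one CPU and is what the tests run; `full` (256 px, 64 base
channels, 200 epochs) mirrors the full-scale configuration. Training is a
deterministic function of the seed. Per-epoch traces record discriminator
loss, generator adversarial loss, the L1 term and a held-out residual
error in T/N units. A generated slice whose dynamic range collapses below
`range_floor` (default 5 of 255) despite brain content is flagged as a
failed reconstruction; brain-free slices are flagged low-content instead.

### Evaluation battery

* **Residual error**: mean ± SD of |ΔT/N| over the brain mask, plus the
  signed mean to expose systematic over/underestimation. The evaluation
  mask defaults to the brain because background voxels would deflate the
  error and inflate SNR meaninglessly.
* **PSNR** `10·log10(255²/MSE)` on the 8-bit scale; **SNR** is the
  reference-energy ratio `10·log10(Σ truth² / Σ (truth − map)²)` — the
  "regular SNR" is not uniquely defined in the literature, and this
  choice is deliberately documented.
* **SSIM** with K₁ = 0.01, K₂ = 0.03, dynamic range 255 and an 11×11
  Gaussian window (σ = 1.5), per slice, valid windows only, averaged over
  mask-intersecting slices; the window shrinks to fit slices smaller than
  11 px.
* **Dice versus threshold**: lesions are `T/N ≥ t` voxel sets; both-empty
  compares as 1, exactly-one-empty as 0.
* **Volume expansion**: `|enhancing ∪ lesion(t)| / |enhancing|`, i.e. how
  much the map expands the treated volume beyond the gadolinium-enhancing
  lesion; always ≥ 1 by construction. A plain-ratio variant sits behind
  `union = FALSE`.
* **VOI statistics**: mean/SD of decoded T/N in a 1-cm³ cube at a
  physical coordinate (voxel centers in the half-open cube), the quantity
  regressed on cell density from image-guided tissue sampling via OLS
  with a two-sided t-test on the slope.

## The phantom: what it emulates and what it does not

The phantom is deliberately geometric, not anatomic: an ellipsoidal
brain, a posterior-inferior ellipsoidal cerebellum (the PET reference
region, kept tumor-free), and a concentric spherical tumor — enhancing
core, nCET rim, edema shell. The pipeline is intensity- and mask-driven,
so geometric realism is irrelevant to its correctness; what matters is
the statistical structure:

* **Latent cell density** peaks at the tumor center (default
  30,000 cells/mm²) and decays linearly to zero at the outer rim
  boundary, giving graded uptake and non-degenerate Dice curves.
* **PET forward model** is affine in density:
  `SUV = baseline + suv_per_cell · density + noise`. Defaults give a
  density-to-T/N slope of 5.8e-5 per cell/mm² at baseline uptake 1.5 SUV
  — the magnitude reported for methionine uptake versus glioblastoma
  cell density in image-guided sampling studies — peaking at T/N ≈ 2.7.
* **MRI carries the density information** the translator must learn: T2
  adds a density-graded component in tumor (peak +40 units) on top of
  the edema/tumor elevation, and T1Gd adds density-graded enhancement
  (peak +80) restricted to the enhancing core. This encodes the premise
  that uptake is predictable from structural MRI; on real data that
  premise is only approximately true, which is exactly why passing
  phantom tests does not certify clinical performance.
* **Inter-institution variability**: each subject draws one global
  multiplicative gain per MRI sequence from `gain_range` (default
  0.5–2). PET takes no gain — T/N normalization is itself tested for
  scale invariance separately.
* **Noise** is additive Gaussian, clipped at zero (the simplest model
  honouring non-negative intensities); defaults SD 2 on MRI units of
  ~100, 0.05 SUV on PET.
* **Geometry jitter** (±15% radii, small center shifts) and noise make
  cohort subjects distinct; everything is a deterministic function of
  the seed, and subject ids embed the cohort seed so cohorts from
  different seeds never collide.
* **Sampling points**: 16 per subject, uniform in the tumor sphere, with
  the analytic density as ground truth — mirroring image-guided tissue
  sampling with known truth.

Not emulated: scanner physics, bias fields, partial-volume effects,
motion, registration error, multifocal tumors, non-enhancing
glioblastoma. Real cohorts also differ in slice thickness and in-plane
resolution (unknown for the motivating cohort); the default grid is
96×96×64 at 2 mm, chosen so full-cohort tests run in minutes, and is
configurable upward.

## Numerical choices

* Histogram mode: equal-width bins on `[min, max]`, top edge closed,
  ties to the lower bin.
* 8-bit quantization: round half up, exactly once, at pair export.
* OLS: closed form via centered sums; residual SD population-normalized.
* Dice empty-set conventions as above; expansion uses the union.
* Instance-normalization ε = 1e-5; Adam ε = 1e-8, β₂ = 0.999; weights
  initialised N(0, 0.02²); all RNG flows from the configured seeds.
* VOI membership: voxel centers in the half-open cube `[lo, hi)`, so an
  aligned 10 mm cube on a 2 mm grid contains exactly 5³ voxels.

## Problem sizes used by the tests

Unit tests run on 48×48×32 phantoms at 3 mm. The end-to-end learnability
check trains the desk preset on a 10-subject low-noise cohort (8 train /
2 test, 200 training pairs after mirroring and subsampling, 10 epochs,
seed-fixed) and then asserts that the held-out residual error at least
halves from the first epoch and that test-subject Dice at T/N 1.5
reaches 0.8. These sizes are the package's chosen study conditions for a
single-CPU workflow; the `full` preset exists for full-scale runs.

## Known limitations

* The translator is a compact reimplementation; it does not reproduce
  any published trained weights, and full-scale (256 px, 200-epoch)
  training on CPU is slow.
* The phantom's MRI→uptake relationship is better determined than in
  real tissue; phantom Dice/residual numbers characterise the pipeline,
  not clinical accuracy.
* zCE discards hypo-enhancement by construction.
* T/N values above 5 are unrecoverable after encoding (flagged, not
  reconstructed).
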