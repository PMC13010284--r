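# gliomapr

Synthesising methionine-PET-like tumor maps of glioblastoma from routine
contrast-enhanced MRI.

## The problem

Glioblastoma infiltrates beyond its gadolinium-enhancing core as
non-contrast-enhancing tumor (nCET), which looks like vasogenic edema on
T2-weighted MRI. Amino-acid PET (¹¹C-methionine) visualises tumor cell
density well enough to separate the two, but it is expensive and rarely
available. `gliomapr` implements, end to end, a pipeline that *learns* the
MRI→PET translation: it turns a subject's T1-weighted, T2-weighted and
gadolinium-enhanced T1 volumes into a tumor-to-normal-ratio (T/N) map — a
"gliomap" — that serves as a surrogate cell-density image, and it ships the
full evaluation battery needed to judge such a map. A synthetic phantom
cohort with known latent cell density makes every stage testable without
patient data.

## The method in brief

1. **Mode-anchored MRI normalization.** For each sequence, with
   `mode(SI₂₅₆bins)` the mode of the 256-bin brain-mask intensity
   histogram,

       SI_normalized = min( SI_original × 75 / mode(SI₂₅₆bins), 255 )

   pinning normal brain tissue to 75 of a 0–255 range, per subject,
   without reference to any cohort statistics.

2. **z-score contrast enhancement (zCE).** One OLS fit of normalized T1Gd
   on normalized T1W over brain voxels defines the subject's
   no-enhancement line; each voxel's residual divided by the global
   residual SD is its z-score, encoded as `clip(z × 51, 0, 255)`.

3. **PET T/N normalization.** SUV divided by the mean cerebellar SUV;
   encoded as `clip(T/N × 51, 0, 255)` (T/N 5 saturates; decoding is
   `pixel / 51`).

4. **Conditional GAN.** Axial slices are packed as RGB = (T1W, T2W, zCE)
   sources against T/N targets, mirrored horizontally for augmentation,
   and split by subject into train/test. A compact pix2pix-style model —
   U-Net generator G, PatchGAN discriminator D — optimises

       G* = arg min_G max_D  L_cGAN(G, D) + λ · E‖y − G(x)‖₁ ,  λ = 100

   with Adam (lr 2e-4, β₁ 0.5). The networks and their backpropagation
   are implemented in this package on Rcpp/Armadillo convolution kernels;
   gradients are verified against finite differences in the tests.

5. **Evaluation.** Residual T/N error (mean, SD, signed mean), PSNR, SNR,
   SSIM, Sørensen-Dice versus T/N threshold, lesion volume-expansion
   ratios over the enhancing mask, 1-cm³ VOI statistics at sampling
   coordinates, and the OLS regression of VOI signal on cell density.

## Worked example

```r
library(gliomapr)

spec    <- phantom_spec(seed = 42)        # 96x96x64 @ 2 mm synthetic subject
subject <- generate_subject(spec, 1)
subject
#> <subject_volume_set> sub-42-001: grid 96x96x64 @ 2x2x2 mm, 16 sampling points

processed <- preprocess_subject(subject)  # normalize -> zCE -> T/N
round(attr(processed$t1w_norm, "mode_value"), 2)
#> [1] 61.6
processed$zce
#> <zce_volume> slope 0.6464, intercept 26.571, residual SD 3.031
processed$tn
#> <tn_volume> cerebellum mean SUV 1.501, T/N range [0.00, 2.71]
```

The histogram mode (61.6 here — this subject drew a global gain of ~0.6)
maps to exactly 75 after normalization, which is what removes the
scanner's arbitrary intensity scale. The zCE fit is the subject's
no-enhancement T1Gd~T1W line; voxels far above it are enhancing tissue.
The cerebellar reference makes normal brain sit at T/N ≈ 1, and this
phantom's tumor peaks at T/N 2.7.

VOI statistics at the subject's 16 simulated tissue-sampling coordinates
regressed on the true cell density:

```r
voi <- vapply(seq_len(16), function(i)
  voi_statistics(processed$tn$tn_values,
                 unlist(subject$sampling_points[i, c("x", "y", "z")]))$mean_tn,
  numeric(1))
density_regression(tibble::tibble(cell_density = subject$sampling_points$true_density,
                                  voi_mean_tn = voi))
#> <density_regression> T/N = 4.95e-05 x density + 1.05 (r = 0.99, P = 9.65e-14, n = 16)
```

The recovered slope (4.95e-5 T/N per cell/mm²) sits slightly below the
generative 5.8e-5 because a 1-cm³ VOI averages over the radial density
gradient — the same attenuation any image-guided sampling analysis faces.

The whole pipeline — phantom cohort, preprocessing, dataset assembly,
training the desk-scale translator, map generation and evaluation — runs
in a few minutes on one CPU:

```r
res <- run_pipeline(pipeline_config(
  seed = 1,
  phantom = list(spec = phantom_spec(noise_sd = c(t1w = 1, t2w = 1,
                                                  t1gd = 1, pet = 0.02),
                                     seed = 1),
                 n_subjects = 10)))
res$model$trace[c(1, 10), ]
#>   epoch loss_d loss_g_adv loss_l1 val_residual_tn
#>       1 0.188        3.23  0.158            0.298
#>      10 0.0845       3.73  0.0153           0.0895
res$summary[, c("subject_id", "ssim", "dice_1p5")]
#>   subject_id  ssim dice_1p5
#> 1 sub-1-006  0.845    0.793
#> 2 sub-1-008  0.846    0.849
```

The held-out residual error falls from 0.30 to 0.09 T/N over ten epochs,
and the generated maps overlap the true T/N ≥ 1.5 lesion at a mean Dice
of 0.82 — on a phantom whose MRI fully determines uptake, so these
figures characterise the pipeline, not clinical performance.
`autoplot(res$model)` and `autoplot(res$reports[[1]])` plot the training
trace and the Dice/expansion curves; `tidy()`/`glance()` methods return
the same quantities as tibbles.

## Package layout

* `phantom_spec()`, `generate_subject()`, `generate_cohort()` — synthetic
  cohorts with ground-truth density and masks
* `brain_histogram_mode()`, `normalize_intensity()`, `normalize_mri()` —
  8-bit mode-anchored normalization
* `fit_t1gd_on_t1w()`, `zce_map()` — contrast-enhancement z-scores
* `tn_normalize()`, `tn_decode()` — PET T/N encoding and its inverse
* `preprocess_subject()`, `build_pairs()`, `mirror_augment()`,
  `split_cohort()`, `write_pairs()` — dataset assembly
* `gan_config()`, `gan_preset()`, `gan_train()`, `generate_gliomap()` —
  the conditional translator
* `residual_error()`, `image_quality()`, `dice_vs_threshold()`,
  `volume_expansion()`, `voi_statistics()`, `density_regression()`,
  `evaluate_subject()` — the evaluation battery
* `read_volume()`, `write_volume()`, `write_subject()`, `read_subject()`,
  `pipeline_config()`, `run_pipeline()` — NIfTI I/O and the driver;
  `inst/cli/gliomap.R` is a thin command-line wrapper

The methods vignette (`vignettes/gliomapr-methods.Rmd`) documents the
model, its assumptions, every tunable parameter and the design decisions
in detail.
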