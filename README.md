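# voxelboost

Binary diagnosis from cohorts of same-shape 3D volumetric images (e.g.
structural brain MRI in NIfTI format, as in Alzheimer's disease vs. normal
control studies), built from two stages:

1. **Group-difference denoising.** From the training cohort only, compute
   the two groups' voxelwise mean images `Ḡ_x(a,b,c) = (1/m) Σ s_i^x(a,b,c)`,
   their difference `D = Ḡ_x1 − Ḡ_x2`, normalize `|D|` by its maximum, keep
   the voxel set `R = {p : D̃(p) > α}`, and crop *every* volume (train and
   test) to the tight bounding box of `R`. Uninformative noisy margins are
   discarded before any network sees them; on the reference full-scale
   geometry (192 × 192 × 160 cropped to 160 × 160 × 120) this removes
   ~47.9 % of the voxels.
2. **Boosted 3D convolutional diagnosis.** `K` small VGG-style 3D networks
   (3 × 3 × 3 convolutions + batch norm + ReLU, 2 × 2 × 2 max pooling,
   fully connected layers with dropout, softmax) are trained in sequence
   under the discrete-AdaBoost recursion: uniform sample weights
   `w_i = 1/N`, weighted error `e_k = Σ w_i 1[C_k(x_i) ≠ y_i]`, fusion
   weight `α_k = ½ ln((1−e_k)/e_k)`, multiplicative reweighting
   `w_i ← w_i exp(−α_k y_i C_k(x_i)) / Z_k`, and each network minimizes the
   sample-weighted cross-entropy
   `(1/N) Σ −w_i [y_i log p_i + (1−y_i) log(1−p_i)]` with Adam. Prediction
   fuses hard votes, `f(x) = Σ_k α_k C_k(x)`.

The network forward/backward passes, Adam and the weighted loss are
implemented in compiled code under `src/`; no external deep-learning runtime
is required. A synthetic phantom generator (ellipsoidal foreground, planted
spherical lesion, pure-noise boundary band, known ground-truth mask) makes
every stage testable end to end, and confusion-matrix metrics plus
rank-statistic AUC close the loop.

## Worked example

```r
library(voxelboost)
co  <- generate_cohort(phantom_config(n_per_class = 20, noise_sd = 0.2,
                                      seed = 42))
run <- run_pipeline(co, alpha = 0.5, k_rounds = 4, seed = 1)
print(run)
print(run$denoiser)
summary(run$model)
```

```
Pipeline run (alpha = 0.5 , K = 4 , denoise = TRUE )
  train/test: 28 / 12
accuracy 1.000  sensitivity 1.000  specificity 1.000  auc 1.000
Crop mask (alpha = 0.5 )
  grid: 32 x 32 x 24  preserved voxels: 280
  crop box widths: 8 x 8 x 8
  voxel reduction: 97.9%
Boosted ensemble fit
 round weighted_error fusion_weight
     1              0      11.51293
     2              0      11.51293
     3              0      11.51293
     4              0      11.51293
```

Reading it: the cohort was split 7:3 per label; the denoising mask, fitted
on the 28 training volumes, preserved 280 voxels — exactly the planted
lesion — and cropped every volume from 32 × 32 × 24 down to the lesion's
8 × 8 × 8 bounding box (97.9 % of voxels removed; this synthetic phantom has
far more uninformative margin than real MRI). Each boosting round then
separated the cropped training set perfectly (weighted error 0, fusion
weight clamped at ½ ln((1−10⁻¹⁰)/10⁻¹⁰) ≈ 11.5), and the fused ensemble
classified all 12 held-out volumes correctly. On harder cohorts the errors
are nonzero, the fusion weights differ per round, and misclassified samples
visibly gain weight between rounds (`run$model$weight_history`).

Other entry points: `denoise_cohort()` (the fitted crop as a reusable
transform), `fit_ensemble()` with any trainer (`cnn_trainer()`,
`stump_trainer()`), `network_shape_trace()` (layer-by-layer shape table),
`ablation_grid()` (α × K sweeps), `export_cohort()`/`load_manifest()` for
NIfTI + CSV round trips, and a thin command-line wrapper in
`inst/cli/voxelboost.R` with `synth`, `denoise`, `run` and `ablate`
subcommands.

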