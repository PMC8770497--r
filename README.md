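# mafcdn — microaneurysm segmentation in FFA images with FC-DenseNets

Microaneurysms (MAs) — tiny focal dilations of retinal capillaries — are the
earliest visible lesion of diabetic retinopathy. In fundus fluorescein
angiography (FFA) they appear as bright round spots a few pixels across,
easily confused with the far larger vessel tree and vastly outnumbered by
background: well under 1 % of pixels in a frame are lesion. `mafcdn` is an R
package for detecting them by semantic segmentation, aimed at people building
or studying retinal-screening pipelines who want a self-contained, CPU-only,
fully reproducible implementation.

The pipeline has two stages:

1. **Preprocessing.** Linear histogram stretching maps each frame's observed
   intensity range `[I_min, I_max]` onto a target range `[G_min, G_max]`
   (default the full 8-bit range),

   `I' = (G_max − G_min) (I − I_min) / (I_max − I_min) + G_min`,

   followed by Gaussian filtering with a discrete kernel
   `w(x, y) ∝ exp(−(x² + y²) / 2σ²)` normalized to sum 1, convolved with
   mirror padding.

2. **Segmentation.** A fully convolutional DenseNet: dense blocks (each
   layer = batch norm → ReLU → 3×3 conv producing `growth_rate` new feature
   maps → dropout) alternate with transition-down layers (1×1 conv + 2×2 max
   pool) on the encoder path and transition-up layers (stride-2 3×3
   transposed conv) on the decoder path, with resolution-matched skip
   concatenations. Connectivity is asymmetric: encoder dense blocks
   concatenate input with output (linear feature-map growth), decoder blocks
   forward only their new maps. Training minimises the focal loss

   `FL(p_t) = −α_t (1 − p_t)^γ log p_t`,

   where `p_t` is the predicted probability of a pixel's true class;
   `γ > 0` down-weights the easy, overwhelmingly background pixels so the
   rare lesion pixels drive the gradient. `γ = 0` with unit weights recovers
   plain cross-entropy.

Evaluation uses six pixel-level metrics computed from the 2×2 confusion
table: pixel accuracy (PA), mean per-class pixel accuracy (MPA), precision,
recall, F1 and mean intersection-over-union (MIoU), reported per image and
aggregated as mean ± sd over a test set.

Because clinical FFA data cannot be redistributed, the package ships a
synthetic FFA scene generator (dark background, smooth illumination field,
curvilinear vessels, low-contrast lesion discs placed near vessels, Gaussian
noise, optional contrast compression) with exact ground-truth masks, so the
entire pipeline — training included — runs from nothing on one CPU. The
training engine (convolutions, normalization, pooling, transposed
convolutions, backpropagation, RMSprop) is implemented in the package itself
on RcppArmadillo; no external deep-learning framework is required.

## Worked example

```r
library(mafcdn)

# a synthetic FFA frame with ground truth
s <- generate_sample(scene_preset("easy", height = 64, width = 64,
                                  n_mas = 3, n_vessels = 2, seed = 7))
s
#> <synthetic_sample 64x64, 3 MA(s), 34 positive pixel(s)>

# a small dataset and a short training run
data_dir <- file.path(tempdir(), "ffa")
generate_dataset(scene_preset("easy", height = 64, width = 64,
                              n_mas = 3, n_vessels = 2, seed = 7),
                 n_train = 40, n_val = 8, n_test = 8, out_dir = data_dir)
fit <- fcdn_train(data_dir, run_config(model = "tiny", loss = "focal",
                                       epochs = 2, seed = 1))
fit
#> <fcdn_fit 'tiny', loss focal, preprocessing on>
#>   epochs run: 2  best val MIoU: 0.8176 (epoch 2)

# predict the held-out frames and score them
pred_dir <- file.path(tempdir(), "pred"); truth_dir <- file.path(tempdir(), "truth")
predict_masks(fit, file.path(data_dir, "test"), pred_dir)
dir.create(truth_dir)
tf <- list.files(file.path(data_dir, "test"), pattern = "_mask")
file.copy(file.path(data_dir, "test", tf), file.path(truth_dir, tf))
evaluate_masks(pred_dir, truth_dir)$summary
#> <metrics_summary over 8 image(s)>
#>   PA     99.61 +/- 0.21 %
#>   MPA    83.00 +/- 6.71 %
#>   Pre    97.00 +/- 5.08 %
#>   Re     66.02 +/- 13.43 %
#>   F1     77.69 +/- 9.74 %
#>   MIoU   82.01 +/- 6.51 %
```

Even two epochs on forty tiny frames segment the easy synthetic lesions
reasonably well: PA is near 1 because background dominates; recall is the
weak spot (small lesions are partially missed), which is exactly the
imbalance the focal loss targets in longer runs. Metrics on a hand-filled
confusion table:

```r
compute_metrics(matrix(c(90, 3, 5, 2), 2, 2))   # truth rows [[90, 5], [3, 2]]
#> <metrics_report>
#>    PA   MPA   Pre    Re    F1  MIoU
#> 92.00 67.37 28.57 40.00 33.33 55.92
```

A command-line wrapper with `synth`, `preprocess`, `train`, `predict`,
`evaluate` and `ablate` subcommands is installed at `inst/cli/mafcdn.R`
(`system.file("cli", "mafcdn.R", package = "mafcdn")`).

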