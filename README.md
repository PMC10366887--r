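# unetu

Denoising of multi-energy photon-counting micro-CT reconstructions in R.

Photon-counting CT sorts photons into energy bins by comparator thresholds,
enabling voxel-wise K-edge material decomposition — but fast analytic
reconstructions (weighted filtered backprojection) are noisy, worst in the
high-energy bins, and that noise corrupts the decomposition. This package
implements a supervised-learning pipeline that maps noisy spectral volumes
toward their low-noise counterparts, for researchers working with preclinical
spectral CT who want a fast surrogate for iterative reconstruction together
with the surrounding machinery: decomposition, baselines, metrics, and a
synthetic benchmark.

The core pieces:

* **Invertible spectral transform** (`forward_transform()` /
  `inverse_transform()`): divide each energy channel by its noise variance
  (robust MAD-of-gradients estimate), take an SVD along the energy dimension,
  high-pass filter each left-singular image (3D Gaussian, 37³ voxels,
  FWHM 10) and normalize by its absolute 99.95th percentile. Affine for a
  fixed state, hence exactly invertible — per axial slice if desired.
* **2D U-net denoisers** (`build_unet()`, `predict_volume()`, `train()`):
  a residual reconstruction-domain baseline trained with MSE, and a
  transform-domain network with `tanhshrink` output trained with a four-term
  loss

  `L = ‖X − X_lab‖²/N + λ₁‖U − U_lab‖²/N + λ₂‖XM⁻¹ − X_lab M⁻¹‖²/N + ‖X_blur − X_blur,lab‖²/N`

  (λ₁ = 15, λ₂ = 0.2) penalizing error in the reconstruction, transform,
  material-decomposition and blurred-reconstruction domains. Forward,
  backward and Adam are implemented in the package (no deep-learning
  framework), with compiled im2col/GEMM convolution kernels.
* **Material decomposition** (`decompose()`, `decompose_nonneg()`,
  `fit_sensitivity()`): `C = X M⁻¹` voxelwise, sensitivity matrices
  calibrated from vials of known concentration, non-negativity by
  Lawson–Hanson active-set least squares.
* **ME NLM baseline** (`me_nlm_volume()`): joint multi-energy non-local
  means (11³ search window, 3³ patches, h = 1.2, per-energy σ from a water
  ROI, 31-slice stacks).
* **Metrics** (`rmse_hu()`, `roi_bias_noise()`, `ssim_psnr()`) and a
  **synthetic phantom generator** (`vial_phantom_template()`,
  `compose_phantom()`, `add_noise()`, `make_paired_dataset()`) so everything
  runs without scanner data.

## Worked example

Generate a paired synthetic benchmark, train the reduced transform-domain
network, and evaluate on the held-out volume:

```r
library(unetu)

M     <- build_sensitivity_matrix(c("water", "I", "Gd", "Ta"))
tmpl  <- vial_phantom_template(c(48L, 64L, 64L), materials = c("I", "Gd", "Ta"))
seeds <- withr::with_seed(1, sample.int(1e6, 12))
pairs <- lapply(1:6, function(i) {
  ph <- compose_phantom(unetu:::vary_phantom(tmpl, seeds[2 * i - 1]), M)
  list(clean = ph$volume, maps = ph$maps,
       noisy = add_noise(ph$volume, noise_spec(default_noise_std(4), seeds[2 * i])))
})
volumes <- lapply(pairs, function(p) {
  ft <- forward_transform(p$noisy)
  list(U_in = ft$U, U_label = project_label(p$clean, ft$state), state = ft$state)
})

net <- build_unet(net_config(levels = 3, base = 16, in_ch = 4, out_ch = 4,
                             activation = "tanhshrink"), seed = 1)
fit <- train(net, volumes, train_config(max_epochs = 20, seed = 1),
             loss = "unetu", loss_cfg = loss_config(M))

vp  <- pairs[[6]]                     # held-out validation volume
ft  <- forward_transform(vp$noisy)
den <- inverse_transform(unclass(predict_volume(fit$net, ft$U)), ft$state)
wmu <- M$mat["water", ]
cat(sprintf("RMSE vs clean: noisy %.1f HU -> denoised %.1f HU (-%.0f%%)\n",
            rmse_hu(vp$noisy, vp$clean, wmu), rmse_hu(den, vp$clean, wmu),
            100 * (1 - rmse_hu(den, vp$clean, wmu) / rmse_hu(vp$noisy, vp$clean, wmu))))
print(round(rbind(noisy    = rmse_maps(decompose_nonneg(vp$noisy, M), vp$maps),
                  denoised = rmse_maps(decompose_nonneg(den, M), vp$maps)), 3))
```

On this desk-scale benchmark (a few minutes of single-core training) the run
prints:

```
RMSE vs clean: noisy 166.8 HU -> denoised 81.4 HU (-51%)
         water     I    Gd    Ta
noisy    0.101 1.140 1.161 1.805
denoised 0.022 0.774 0.586 0.988
```

i.e. volume RMSE against the clean reference roughly halves and the
non-negative decomposition improves for every material (water in g/mL,
contrast agents in mg/mL). A command-line interface wrapping the same
functions is in `inst/cli/unetu` (`simulate`, `transform`, `train`,
`denoise`, `menlm`, `decompose`, `evaluate`).

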