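---
title: "Denoising multi-energy photon-counting micro-CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising multi-energy photon-counting micro-CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Photon-counting detectors sort x-ray photons into energy bins by comparator
thresholds, so a single scan yields simultaneous multi-energy images and, with
thresholds placed just above the K-edges of contrast agents (I, Ba, Gd, Ta,
Au, Bi), voxel-wise basis-material decomposition. The price is noise: dose
constraints and photon binning leave fast analytic reconstructions (weighted
filtered backprojection, wFBP) noisy, especially in high-threshold bins.
Regularized iterative reconstruction removes this noise with low bias but is
slow. This package implements a supervised-learning surrogate: a 2D U-net
that maps noisy spectral volumes toward their low-noise counterparts, plus
everything needed around it — an invertible spectral preprocessing transform,
a four-term training loss, image-domain material decomposition, a
multi-energy non-local means (ME NLM) baseline, image-quality metrics, and a
synthetic phantom generator so the whole pipeline is testable without scanner
data.

All volumes are `Z × Y × X × E` arrays of linear attenuation (cm⁻¹) with
1-based voxel indices and axial slices along the first axis.

## The spectral model and material decomposition

Each voxel's spectral attenuation is modelled as a linear combination of
basis materials,

$$X(e) = C_{H_2O} M_{H_2O}(e) + C_{Ca} M_{Ca}(e) + \sum_i C_i M_i(e),$$

where $M$ is the materials-by-energies sensitivity matrix (attenuation per
unit concentration, calibrated by fitting the slope of ROI attenuation versus
known vial concentration) and $C$ holds concentrations — g/mL for water,
mg/mL for everything else. Decomposition solves $C = X M^{-1}$ voxelwise:
exactly for square $M$, by minimum-norm least squares when there are more
energies than materials. Negative concentrations are physically meaningless;
`decompose_nonneg()` projects each violating voxel onto a subspace of
non-violating basis materials. We implement this as the Lawson–Hanson
active-set non-negative least squares, which provably attains the optimum of
$\min_{c \ge 0} \lVert cM - x \rVert$; an exhaustive search over all material
subsets serves as the independent oracle in the tests. Two calibration
choices worth noting:

* vials are aqueous solutions, so the water background attenuation is
  subtracted before slope fitting — this makes compose → calibrate round
  trips exact on noiseless phantoms;
* the units convention above is fixed throughout (water g/mL, others mg/mL).

## The invertible spectral transform

The network does not see raw attenuation. Each volume is preprocessed by:

1. dividing every energy channel by its noise **variance**, estimated
   robustly as $\sigma = 1.4826\,\mathrm{MAD}(\nabla I)/\sqrt 2$ from
   first-order finite differences of the central axial slice (the difference
   of two i.i.d. variables has twice their variance; the estimate is floored
   at machine epsilon so constant channels cannot divide by zero);
2. a singular value decomposition along the energy dimension of the
   (voxels × energies) matrix, keeping the left-singular images;
3. high-pass filtering each left-singular image by subtracting a
   3D-Gaussian-blurred copy of itself (kernel 37³ voxels, FWHM 10 voxels,
   σ = FWHM/2.3548, mirror boundary, kernel clipped to the grid and
   renormalized);
4. dividing each component by the 99.95th percentile of its absolute values,
   computed over the whole 3D component.

Variance weighting equalizes channels across threshold settings; the SVD
decorrelates them; the high-pass makes inputs zero-centered (high-frequency
content is also the part most consistent across threshold settings); the
percentile scaling brings component variances near the scale network
initialization assumes. Every step is affine for a fixed state, so the
transform inverts exactly — per axial slice if desired — by rescaling, adding
back the stored low-pass content, mapping through $SV^\top$, and multiplying
by the variances. The state (variances, singular values and vectors, low-pass
volumes, scales) is a first-class object with its own serialization.

Design choices made where more than one convention exists:

* **SVD sign convention**: the largest-magnitude entry of each right singular
  vector is forced positive, so transforms are reproducible across runs and
  LAPACK builds. The training augmentation then flips signs deliberately.
* **Label projection**: a clean label volume is mapped through the *input's*
  state (its variances, singular vectors and scales), but high-pass filtered
  by subtracting the label image's own blur. Projecting the input through its
  own state reproduces its transform exactly, a self-consistency the tests
  pin down.
* **Inversion adds back the input's low-pass content**: the network predicts
  only high-frequency structure; low frequencies ride through unchanged.
* Blurs are implemented as explicit banded matrices per axis (separable),
  which keeps them exactly linear with an exact adjoint — needed for the
  analytic loss gradient below.

## Networks and training

Two 2D U-net variants (four levels and two convolutions per level at full
scale; each convolution followed by batch normalization and ReLU; 2×2 max
pooling; 2×2 transposed-convolution upsampling; skip concatenation; a final
1×1 projection):

* **the reconstruction-domain baseline**: input and output are noisy/clean
  attenuation slices, with a residual input→output connection to absorb the
  non-zero-centered intensity scale, trained with MSE;
* **the transform-domain network**: 4-in/4-out channels in the transform
  domain with a `tanhshrink(x) = x − tanh(x)` output activation, which is
  near-zero for small inputs and asymptotically linear, reducing bias at
  large component values.

No deep-learning framework is involved: forward and backward passes are
written out explicitly (im2col + GEMM convolution kernels in compiled code),
and the whole backward pass is verified against central finite differences in
the tests. Filter counts, pooling and upsampling operators are the canonical
U-net choices; the base filter count defaults to 64 and scales down for CPU
work. Residual variants zero-initialize the final projection so they start as
the identity; the transform-domain variant keeps He initialization there
because a near-zero head would stall gradients through tanhshrink at the
origin, where its derivative vanishes.

The transform-domain loss has four terms, each normalized by its own entry
count $N$:

$$\mathcal L = \tfrac1N\lVert X - X_\mathrm{label}\rVert_F^2
 + \lambda_1 \tfrac1N\lVert U - U_\mathrm{label}\rVert_F^2
 + \lambda_2 \tfrac1N\lVert XM^{-1} - X_\mathrm{label}M^{-1}\rVert_F^2
 + \tfrac1N\lVert X_\mathrm{blur} - X_\mathrm{blur,label}\rVert_F^2$$

with $\lambda_1 = 15$, $\lambda_2 = 0.2$ (chosen so the first three terms
have similar magnitude), $X$ obtained from the network output by the exact
per-slice inverse transform, the decomposition term using plain matrix
inversion (no non-negativity constraint — thresholding inside a loss risks
vanishing gradients) of a sensitivity matrix whose rows are rescaled by their
calibration vial concentrations so all material maps sit on a similar scale,
and the fourth term blurring each energy channel with a 19×19 / FWHM-5 2D
Gaussian to penalize low-frequency bias. Because everything linking $U$ to
$X$ is affine and the blurs have exact adjoints, the gradient with respect to
the network output is analytic; the tests check it against finite
differences.

Training follows a fixed protocol: one whole volume held out for validation,
slices shuffled, random horizontal/vertical flips (probability 0.5 each) plus
random sign flips of singular-vector components (0.5, transform-domain only,
applied consistently to input, label, and state), Adam at an initial learning
rate of 2×10⁻⁴ with batch size 8, up to 2000 epochs, the learning rate halved
whenever the validation loss sets no new minimum for 10 consecutive epochs,
and training stopped after 20 such epochs. "Fails to decrease" is read as "no
new running minimum" with both counters running concurrently, and the
best-validation parameters are restored at the end (the alternative — keeping
the final weights — is not what early stopping is for).

## The ME NLM baseline

The non-data-driven comparator filters each voxel as a weighted average over
an 11³ search window with weights
$w_{ij} = \exp(-\sum_e d_e(i,j) / (2h^2\sigma_e^2\lvert P\rvert))$, where
$d_e$ is the squared distance between 3³ patches at energy $e$,
$h = 1.2$, $\sigma_e$ is measured in a homogeneous water ROI, and the same
weights filter every energy jointly. It is applied to 31-slice stacks,
keeping the 16th slice each time, with mirror reflection past the volume
ends. Conventions the literature leaves open — the exact weight kernel, the
self-weight of the center voxel (computed like any other, $d = 0$), and
mirror padding for patches at borders — are pinned by a brute-force
double-loop oracle that the compiled implementation must match to 1e-10.

## The synthetic benchmark

The generator emulates paired scans of vial phantoms: a water cylinder
("body") with contrast vials (aqueous solutions, so vials carry the water
background plus their agent), composed exactly through the forward model, and
a noisy copy with additive zero-mean Gaussian noise, independent per voxel
and energy. Defaults define the benchmark conditions:

* 4 energy bins, 48 × 64 × 64 voxel volumes (desk scale; the full 400 × 400
  in-plane size is a configuration option), 0.125 mm voxels;
* noise standard deviations (0.02, 0.03, 0.045, 0.065) cm⁻¹ across the four
  bins — noise rising with threshold energy, equivalent to roughly 80–260 HU
  of water-vial noise, matching the regime where high bins are
  photon-starved;
* dose-reduction series emulated by scaling the noise by √factor for
  undersampling factors 1–6, with all factors sharing one noise realization —
  undersampling one scan keeps dose levels strongly correlated, which
  independent draws would not reproduce (projection-domain undersampling
  itself is out of scope);
* synthetic sensitivity curves: a decaying water curve and K-edge-like steps
  switching on at each agent's K-edge, so bins are spectrally separable and
  the 4×4 system is well conditioned.

What the generator deliberately does not model: reconstruction noise texture
(real wFBP noise is spatially correlated by the ramp filter; ours is white),
partial-volume effects at object boundaries (voxel-center membership keeps
the ground truth exact), beam hardening, and detector spectral distortions
(charge sharing, pulse pileup). Passing tests on this benchmark therefore
demonstrate the correctness and internal consistency of the pipeline and the
qualitative orderings between methods, not scanner-grade performance numbers.

## Desk-scale experiment sizes

The built-in end-to-end experiment trains a reduced transform-domain network
(3 levels, base 16 filters, ≈118k parameters) for 20 epochs on 5 training +
1 validation synthetic volumes (240 training slices, batch 8). On this
benchmark the trained network cuts volume RMSE against the clean reference by
roughly half relative to the noisy input, improves the non-negative
decomposition RMSE for every material, and its SSIM/PSNR against the clean
reference fall monotonically along the dose series — the orderings expected
of a working implementation. The acceptance script
(`scripts/acceptance.R`) reruns exactly this experiment from scratch.

## Numerical notes and limitations

* Tolerances: transform round trips hold to ~1e-12 in double precision
  (asserted at 1e-4, the float32 criterion); decomposition round trips to
  1e-10 relative; the NNLS active-set tolerance is 1e-10 on concentrations.
* Degenerate inputs: constant channels floor their noise variance at machine
  epsilon; zero volumes produce zero singular values, which `project_label()`
  rejects explicitly; percentile scales are floored likewise.
* The scheduler interprets patience strictly (counters reset only on a new
  strict minimum); scripted-sequence tests pin the exact halving and stopping
  epochs.
* Training on CPU in R is the main cost; problem sizes above were chosen so
  the full suite runs on a laptop-class single core. Larger grids and filter
  counts scale as expected but are not exercised by the tests.
* `decompose()` masks `stats::decompose()` when the package is attached;
  call `stats::decompose()` explicitly if you need classical time-series
  decomposition in the same session.
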