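---
title: "Methods: patch-based retinal vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based retinal vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(retseg)
```

This vignette documents the model the package implements, the choices that
were genuinely open when building it, and what the test suite does and does
not establish. Code chunks are illustrative (`eval = FALSE`); the worked
example in the README shows real output.

## The segmentation problem

Retinal vessels are thin, branching, low-contrast curvilinear structures
photographed against unevenly illuminated tissue inside a circular
field of view (FOV); everything outside the FOV is near-black camera
background. Segmentation is pixel-level binary classification, heavily
imbalanced (vessels are roughly 3–15% of FOV pixels). The pipeline treats
the problem patch-wise: small windows normalize the learning problem across
image sizes and multiply the effective training-set size.

## Preprocessing

The chain is green channel → Gaussian denoise → FOV-restricted histogram
equalization → gamma transform, returning a single-channel image in [0, 1].

* **Green channel.** The sensor's green band carries the strongest
  vessel/tissue contrast; red saturates and blue is noisy. One source
  passage describes a grayscale conversion while the detailed description
  selects the green channel; the package follows the explicit channel
  selection.
* **Gaussian filter** (`kernel = 3`, `sigma = 1`, reflective borders).
  The filter size is not fixed by the protocol; the smallest standard
  kernel was chosen because vessels of 1–2 px would be destroyed by
  anything wider. Both parameters are configurable
  (`preprocess.gaussian.*`). Whether denoising precedes or follows channel
  selection is ambiguous in the protocol's wording; the package smooths the
  already-extracted green channel, which is equivalent for a linear filter
  applied channel-wise and cheaper.
* **Masked equalization.** The discrete transfer function
  `s_k = round((L-1) * cumsum(n_j/n))` uses counts over FOV pixels only;
  a global equalization would let the huge black background dominate the
  histogram and crush tissue contrast. Rounding is half-up
  (`floor(x + 0.5)`), fixed so results are exactly reproducible; base R's
  banker's rounding would map 127.5 to 128 but 62.5 to 62. Pixels outside
  the mask are set to 0, matching the observation that background stays
  near black and preventing background leakage into border patches.
* **Gamma transform** (`gamma = 1.3`, `c = 1`) applied on the
  [0, 1]-normalized equalized image, where the power law is defined.
  `gamma > 1` darkens midtones, deepening vessels against the equalized
  tissue.
* **FOV masks.** DRIVE-style datasets ship masks; STARE-style do not. When
  absent, the mask is estimated as: threshold the mean channel at half the
  Otsu cut (half, because the shaded disc rim and dark vessels fall below
  the raw Otsu threshold while the background sits far below half of it),
  keep the largest connected component, fill holes, and close with a 7-px
  disc so vessel-induced channels to the boundary do not survive. On
  synthetic images this recovers the generating disc with Jaccard > 0.99.

## Patch preparation

Images are zero-padded bottom/right to multiples of 64 and cut by a 64-px
window sliding at step 16, left to right, top to bottom. For the stated
dataset geometries the grid closes exactly (584×584 → 640×640 → 37² = 1,369
patches; 605×700 → 640×704 → 37×41 = 1,517); for arbitrary sizes the
padding is extended to the next size where `(dim - window) %% step == 0`,
which preserves those counts and generalizes cleanly. Each epoch every
patch is re-augmented: independent 50% horizontal/vertical flips, rotation
by a random multiple of 90° (free-angle rotation would blur binary labels
through interpolation), and a random crop of side fraction ≥ 0.8 resized
back bilinearly, with labels re-binarized at 0.5. The crop range is not
fixed by the protocol; 0.8 keeps most context while still jittering scale.

At inference the same grid is reused and overlapping patch predictions are
averaged, which suppresses patch-border seams; the threshold (default 0.5,
configurable) is applied after stitching.

## Network

Input and output are 64×64×1 (any window divisible by 8 works). The
encoder has three stages with channel widths 64/128/256, each a residual
block followed by 2×2 max pooling. A residual block computes
`H(x) = F(x) + g(x)` where `F` is conv3×3–BN–ReLU–dropout(0.2)–conv3×3–BN–ReLU
and `g` is an always-present 1×1 convolution adjusting channels. The middle
stage is followed by a residual attention module `H = (1 + M)·T`: a
two-convolution trunk with a jump connection, and a mask branch that pools
twice, convolves once per resolution level, upsamples twice by transposed
convolution and ends in a 1×1 convolution + sigmoid. The deepest stage is
followed by ASPP: a 1×1 branch (rate 1) and three 3×3 dilated branches
(rates 2/3/4), 128 kernels each with BN+ReLU, concatenated to 512 channels.

The decoder mirrors the encoder: transposed-convolution upsampling (2×2,
stride 2), concatenation of the matching encoder stage's output (skip
connection), then a residual block. With the default widths the decoder
output is exactly 64×64×64, after which a final residual block, a 1×1
convolution and a sigmoid give the probability map. One design point was
genuinely open: listing the decoder stage as upsample → residual → concat
cannot produce a 64-channel pre-output map (the final concatenation would
leave 128 channels), so the package concatenates before the residual block,
the ordering that meets the stated 64×64×64 contract; both the attention
and ASPP placements are configurable (`attention_stage`, `aspp_stage`).

Three deep-supervision heads tap the encoder stage outputs (scales 1, 2, 4
relative to the input). What distinguishes the three heads is unspecified
beyond "different layers and blocks"; the package uses depth-matched
chains — one transposed convolution + ReLU per halving, channel widths
stepping down through the stage widths — ending in a 1×1 convolution and
sigmoid. At inference only the main output is used; the heads are a
training aid.

## Loss and training

Each of the four outputs is scored by class-weighted binary cross-entropy
with natural logarithms, weights `∂ = X⁻/m` (vessel term) and `1 − ∂`
(background term) computed from the batch target — per batch rather than
per dataset, matching the per-input definition of `m`; predictions are
clamped to `[1e-7, 1 − 1e-7]` before the logs. The total loss combines the
components with the schedule `β = 1 − epoch/epochs`. The printed form of
the combination multiplies all four losses by β, which would drive the
total — and every gradient — to zero at the final epoch; the surrounding
description says β weights the deep-supervision losses. The package
default is therefore `β·(l1+l2+l3) + l4`, and a `loss_mode = "strict"`
flag reproduces the printed formula verbatim. For the same reason the
training-sanity checks assert the loss decrease on the main-output loss
`loss4`, which the schedule does not rescale.

Optimization is Adam (lr 0.001, β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — the
conventional defaults, recorded in the run log) with batch 20 for
500 epochs at full scale. L2 regularization of strength 1e-4 is applied to
convolution kernels only, implemented as a gradient penalty `2λw`; its
strength is configurable (`model.l2_coeff`). Patches are shuffled globally
across images each epoch. A 90/10 validation split is available for
diagnostics (`val_fraction`, logged per epoch); early stopping is never
applied, honoring the fixed-epoch protocol. Runs are deterministic given
`seed`: initialization, shuffling, augmentation and dropout all derive from
it.

Numerical choices: He initialization (sd `sqrt(2/fan_in)`); batch norm with
momentum 0.9 and ε = 1e-5 on running statistics, batch statistics in
training mode; inverted dropout so inference needs no rescaling; max-pool
ties broken by first occurrence in column-major order. The network itself
is implemented on a small reverse-mode autograd with compiled kernels for
(dilated) convolution, transposed convolution, pooling and batch norm;
gradients of every operator are verified against central finite differences
in the test suite to relative error below 1e-5.

## Synthetic data

The generator emulates what the preprocessing and network need to see:
a disc FOV (radius 0.46·min(h, w)) on near-black background; green-dominant
tissue with quadratic radial shading and low-frequency texture; vessel
trees grown from roots near the disc center as quadratic Bézier segments
with per-generation width decay (≈5–6 px roots down to 1 px), branching
with probability 0.35 to depth 5; strokes rendered 30–60% darker than
tissue in the green channel on a 2× supersampled canvas, re-binarized at
half coverage to give exact ground truth; Gaussian pixel noise (sd 3 of
255). Defaults were chosen once so the vessel fraction inside the FOV lands
in the 2–20% band typical of fundus benchmarks (about 3% at 584×584).

What it does **not** model: optic disc and macula, lesions and exudates,
specular reflections, interlaced illumination gradients, camera vignetting
profiles, or realistic vessel tortuosity and caliber statistics. Passing
tests on synthetic data therefore demonstrate that the pipeline is wired
correctly and can learn dark curvilinear structures from small samples —
not that it reaches benchmark-level accuracy on real photographs.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` run everything at desk scale, a
deliberate choice so the whole pipeline is exercised end to end in minutes:
patch-count reproduction uses full-size synthetic images (20 at 584×584,
10 at 605×700); the training sanity check trains the reduced architecture
(stages 8/16/32, 8 ASPP kernels per branch — `tiny_model_spec()`) on
50 patches from two 128×128 images for 150 epochs with batch 10, then
compares held-out AUC against the untrained network. The full-scale
protocol (default `model_spec()` and `train_config()`) is encoded but not
executed; reproducing the published benchmark figures requires the real
DRIVE/STARE datasets and accelerator-scale training.

## Known limitations

* Single-threaded CPU training: practical for reduced models and smoke
  tests, not for the 500-epoch full-scale protocol.
* The FOV estimator assumes one bright, roughly convex region; montage
  images or severe vignetting would need supplied masks.
* GIF input is not supported (no reader in the dependency set); PNG, TIFF
  and PPM/PGM are.
* Binarization uses a single global threshold after stitching; no
  per-image threshold calibration is attempted.
* Metrics default to FOV-restricted evaluation (whole-image evaluation is
  available by passing a full mask); whether published figures are
  FOV-restricted is not always stated, and the two differ because the
  background inflates accuracy and specificity.
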