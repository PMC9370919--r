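---
title: "QR eigenface analysis for motor-imagery EEG: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QR eigenface analysis for motor-imagery EEG: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrefa)
```

## The problem and the representation

Four-class motor imagery (left hand, right hand, foot, tongue) produces
class-specific spatial patterns in multi-channel EEG. `qrefa` classifies
epoched trials by treating each trial's `S x C` slab (time samples by
channels; typically 500 x 60 or 500 x 22 at 250 samples/sec over a 2 s
window) as a grayscale image, and running an eigenface analysis over the
trial stack:

1. **Rasterize.** Each trial becomes a row of the `N x T` data matrix,
   `T = S * C`, by row-major flattening (`rasterize_trials()`).
2. **Center.** The per-pixel mean image `psi` is removed:
   `phi_k = x_k - psi` (`center_stack()`).
3. **Snapshot eigendecomposition.** The covariance eigenproblem is solved in
   trial space: the `N x N` matrix `(1/N) Phi Phi^T` has the same nonzero
   spectrum as the `T x T` pixel covariance, and its eigenvectors
   back-project to pixel-space eigenfaces `Gamma = Phi^T v / ||Phi^T v||`
   (`eigendecompose_snapshot()`). With `T` around 30 000 the dense problem
   is not an option, and — essential here — the *trial-space* eigenvectors
   have length `N`, which is what the QR restructuring step reshapes.
4. **Project.** Training and test trials are projected onto the retained
   eigenfaces, `Omega = Phi Gamma` (`project_trials()`); test trials are
   centered with the **training** mean, never their own.

## From eigenvectors to standardized QR images

The pipeline confines the basis to a class-balanced subset: the first
`trials_common` trials of each class, where `trials_common` is the smallest
per-class count shared by all subjects (`common_trials()`). With
`n_classes * trials_common` trials the top `n_classes` trial-space
eigenvectors reshape row-major onto the most-square grid `H x W` of
`n_classes * trials_common` pixels (`qr_grid_shape()`): 120 pixels give
12 x 10, 288 give 18 x 16. These standardized small images — the QR
eigenfaces, "QR" being a visual metaphor for matrix barcodes, not ISO
encoding — are shared geometry across subjects and domains.

A per-trial QR image is then the linear combination of the QR eigenfaces
weighted by that trial's leading projection coefficients
(`synthesize_qr_images()`). An alternative reading — reshaping the
coefficient vector itself — is available as `mode = "reshape"` for
comparison; the weighted-sum reading is the default because it is the one
stated operationally in the source method description. The
`brightness_factor` (default 1) is cosmetic once images are min-max
normalized downstream; it is kept configurable for parity with the
procedure's step list. Class-to-face assignment defaults to eigenvalue-rank
order, with a supervised mode that gives each class the face maximizing its
mean coefficient magnitude.

`similarity_report()` turns the usual qualitative "train and test QR images
look alike" inspection into numbers: Pearson correlations between
class-matched mean images, summarized as diagonal (matched-class) versus
off-diagonal mean.

## Brightness augmentation

Training QR images are few (hundreds); the CNN wants thousands.
`augment_brightness()` cycles the sources round-robin and multiplies each
copy elementwise by an independent per-pixel factor field `mu + sigma * Z`
with defaults `mu = 1`, `sigma = 0.7`. Two deliberate properties:

* noise is **per pixel**, not a per-image scalar — the factor field has the
  full `H x W` shape;
* factors are **not clipped** at zero (about 7.7% are negative at
  `sigma = 0.7`); an optional `clip_negative` flag exists but is off, and
  re-quantization happens only at CNN input normalization, avoiding double
  quantization loss.

Test images are never augmented; the pipeline asserts this and logs it.
The default augmentation budget is 24 copies per source image (about 10 000
images for the three-subject layout); it is a free configuration parameter,
since no principled multiplier follows from the published counts.

## The minimal CNN

`cnn_config()` preset "A" (default): one 7 x 1 valid convolution
(12 x 10 input -> 6 x 10 feature map), 2 x 2 mean pooling (-> 3 x 5), then
fully connected layers 64 -> 32 -> `n_classes` with softmax cross-entropy.
Preset "B" offers sixteen 9 x 3 filters, the alternative published
configuration. Stated hyperparameters are kept: learning rate 1e-4, batch
size 512, a momentum optimizer. Unstated ones are package choices:

* **Momentum coefficient 0.95.** At learning rate 1e-4 the loss surface of
  this very small network is traversed slowly; 0.95 reaches convergence
  within a few hundred epochs where 0.9 needs thousands.
* **Activation tanh.** No nonlinearity is named in the source. With a
  *single* convolution filter, a ReLU conv unit that goes dead silences the
  entire convolutional stage; tanh is bounded, symmetric and cannot die,
  and proved markedly more robust across seeds. ReLU remains selectable.
* **Early stopping** on a 10% validation split carved from the augmented
  training set, patience 30 epochs, best-validation weights restored;
  `max_epochs` 400.
* **Input normalization**: per-image min-max to [0, 1].

Weight initialization, batch shuffling and the validation split all derive
from one seed; training is exactly reproducible single-threaded. The
forward pass is verified against a loop-based direct-convolution oracle and
the backward pass against central-difference gradients in the test suite.

## Evaluation statistics

Per run, misclassified trials are pooled over subjects:
`success_rate = 1 - sum(failed) / sum(total)`, reported to 6 decimals.
Repeated simulations (default 10, seeds `base_seed + run`) are summarized
by `t_confidence_interval()`: sample SD with the `n - 1` denominator,
standard error, and the exact two-sided Student-t quantile at
`df = n - 1` — about 2.262 at `n = 10`, which common usage rounds to 2.26.
The package computes the quantile rather than hard-coding the rounded
value. `accuracy_table()` reports per-subject percentages and their
*unweighted* mean; note that a trial-weighted pooled rate is a different
quantity and the two disagree whenever subjects contribute unequal trial
counts. (Two published summary cells resist recomputation altogether: the
three-subject QR-EFA row averages 91.39 unweighted / 91.19 weighted against
91.11 printed, and the nine-subject two-class EFA_LDA row averages 52.60
against 52.55 printed even though all its subjects have equal trial counts.
The package reports the recomputed unweighted values in both cases.) The shipped reference tables also carry two alternative 10-run rate
sets for the three-subject benchmark whose published summary statistics
correspond to the first set while the published per-run table matches the
second; `reference_results()` exposes both and the tests reproduce both
computations without resolving the inconsistency.

## The synthetic cohort generator

`synthetic_spec()` emulates the benchmark layouts (three subjects with
45/30/30 trials per class per domain at 500 x 60, or nine subjects with 72
per class at 500 x 22) with the statistical structure the method assumes:

* each class contributes a **rank-1 space-time pattern**: an orthonormal
  class channel vector times a cue-locked carrier (frequency and phase
  drawn once per cohort inside the mu band, 8-12 Hz by default);
* trial-to-trial variation enters through a smooth random amplitude
  envelope and a lognormal trial gain — not through phase scrambling, which
  would make same-class trials orthogonal in pixel space and leave nothing
  for a linear subspace method to find;
* subjects share the class patterns but carry a multiplicative channel-gain
  perturbation of SD `subject_effect` (default 0.2), realizing subject-wise
  similarity as a controllable parameter;
* white Gaussian sensor noise, scaled so signal power / noise power equals
  `snr`; `snr = 0` removes class information entirely.

What passing tests on this generator show: the pipeline recovers linear
class structure embedded per the model above, at the benchmark geometry, and
collapses to chance when no structure exists. What they do not show:
performance on real EEG, which adds 1/f background, nonstationarity,
artifacts, volume-conduction correlation structure and label noise, none of
which are modeled (a deliberate scope choice keeping the snr knob
interpretable).

## Numerical choices and degenerate inputs

* Eigenvector signs are fixed (largest-magnitude pixel positive), flipping
  the trial-space vector together with its eigenface so weighted sums are
  invariant.
* Near-zero eigenvalues are guarded before normalization; `k_max` is capped
  at `N - 1` (centering removes one rank).
* Min-max normalization of a constant image maps to zeros; quantization of
  a constant set divides by 1 instead of 0.
* Prediction ties break toward the lowest class index.
* A prime QR pixel count larger than 3 degenerates to a single-column grid
  with a warning.
* Container round-trips are bit-exact for both dialects (the text dialect
  prints 17 significant digits).

## Problem sizes used by the shipped checks

The unit suite runs on scaled-down cohorts (100 samples x 12 channels,
10/8/8 trials per class) so each pipeline stage is exercised in seconds.
The acceptance-level checks run the full three-subject benchmark geometry
(500 x 60, 45/30/30 per class per domain) at snr 2 and snr 0 over three
seeds each — the sizes at which the end-to-end recovery claims are made —
and use five random instances for the eigen-oracle comparison and 1e5
draws for the augmentation moment check.

## Known limitations

* Real-recording support covers validated containers (rds/tsv dialects);
  raw competition GDF parsing and band-pass prefiltering are out of scope.
* The published headline accuracies on the real competition datasets are
  not reproduction targets here; reproducing them requires the external
  recordings. The package reproduces every piece of *reporting arithmetic*
  from its published inputs instead.
* The CNN is single-threaded CPU code sized for 12 x 10 to 18 x 16 images;
  it is not a general-purpose deep-learning stack.
* Whether the eigenface basis should be pooled across subjects is left
  open in the source; the package defaults to per-subject bases (matching
  the per-subject result tables) and exposes pooling only implicitly by
  concatenating containers upstream.
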