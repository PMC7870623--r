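---
title: "Automated age estimation from knee MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated age estimation from knee MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forensic age estimation asks whether a living person without valid documents
is a minor, and how old they are. In adolescent males the epiphyseal growth
plates of the knee ossify on a well-characterized schedule: the dark
cartilage gap between epiphysis and metaphysis visible on T1-weighted MRI
narrows with age and closes around 18-19 years. `kneeage` implements a
fully automated pipeline that turns a raw 3D knee MR volume into a
chronological-age estimate (regression, in years) and a minor/adult
classification (subjects under 18 are the positive class), with no manual
landmarking or staging.

The pipeline has three parts:

1. **Pre-processing** — every volume is resampled to a common in-plane grid
   (448 x 448 by default), corrected for the smooth multiplicative bias
   field, localized by normalized cross-correlation against a small
   characteristic-region template (the intercondylar notch for coronal
   scans, the posterior-cruciate-ligament region for sagittal scans), and
   cropped to a fixed 130 mm x 130 mm volume of interest spanning all
   slices.
2. **Bone extraction** — an encoder-decoder segmentation network labels
   bone and growth-plate structures per slice; the VOI is masked so only
   age-relevant anatomy survives. The stack is then reduced to exactly 12
   informative slices: slices with at most 2% bone pixels are dropped
   (strict threshold), and the survivors are thinned to 12 by even
   selection anchored at the centre of gravity of the bone-per-slice
   distribution.
3. **Age estimation** — a compact CNN regresses an age from each of the 12
   slices; a tree ensemble (extremely randomized trees for regression, a
   random forest for classification) aggregates the 12 per-slice estimates
   (optionally with anthropometrics and ossification stages) into the final
   subject-level outputs.

Evaluation uses repeated stratified 5-fold cross-validation with
per-fold/per-repeat reporting, and two statistical-reference baselines: the
training-mean constant regressor and the all-minors classifier.

## The age-regression network

The regressor is five "Down Blocks", each two units of
`3x3 conv -> ELU -> batch-norm -> dropout` followed by `2x2 max-pool`, with
channels doubling per block (16, 32, 64, 128, 256) so a 224 x 224 input is
compressed to 7 x 7 x 256. A head of global average pooling, dropout
(p = 0.5) and a single linear unit emits the age. Block dropout grows with
depth d as 0.1 x d and acts on whole feature maps (channel dropout).
The default geometry holds 1,180,721 trainable parameters (1.18 M;
convolution weights/biases and batch-norm scale/shift count, running
moments do not).

```{r}
library(kneeage)
model <- build_agenet2d(agenet_spec(), seed = 1)
count_parameters(model)   # 1180721
```

Training minimizes the mean squared error between predicted and
chronological age over slices (each of a subject's 12 slices inherits the
subject's age) with Adam, learning rate 1e-4, batch size 16, 1000 epochs,
and returns the checkpoint with the lowest validation loss. The encoder can
be transfer-initialized from the segmentation network
(`transfer_init()`), which shares its block layout name-for-name.

The channel plan deserves a note: with two convolutions per block, a plan
that both "starts at 8" and "ends at 256" under per-block doubling cannot
exist. We treat the parameter total as authoritative: base width 16 per
block reproduces both the 256-channel bottleneck and the 1.18 M total,
while a base of 8 would give roughly half as many parameters.

## The segmentation network

`build_segnet()` mirrors the age network's encoder and adds a symmetric
decoder with 2 x 2 stride-2 transposed-convolution upsampling and skip
connections, closing with a 1 x 1 convolution and sigmoid. Training uses
binary cross-entropy plus soft Dice with Adam (lr 1e-3, batch 16), early
stopping on validation loss with patience 10, over a random 70/15/15
subject split. A coronal model is adapted to sagittal data by
`finetune_sagittal()`: exact weight copy, then 5 further epochs.

The network engine itself (convolutions, pooling, batch norm, dropout,
Adam) is implemented in the package with Rcpp/Armadillo kernels; every
layer's backward pass is validated against central finite differences in
the test suite, and the convolution forward pass against a naive R
reference.

## The synthetic phantom cohort

Clinical knee MRIs cannot ship with a package, so `generate_cohort()`
produces phantoms carrying a recoverable age signal:

- three bright bone analogues (femur, tibia, fibula — the fibula only on
  coronal phantoms) built from ellipsoids, each split by a dark
  growth-plate band;
- the band's width falls **linearly** from `gap_max_mm` (default 8 mm) at
  age 13 to zero at the closure age (default 19 y), with per-subject
  lognormal variation (`gap_sdlog`, default 0.1; set 0 for the exactly
  monotone construction used in tests);
- a smooth multiplicative quadratic bias field, additive Gaussian noise,
  and per-subject in-plane pose jitter;
- ground-truth bone masks (the dark gap is *not* part of the mask, so
  masked images show bones separated by the age-dependent gap);
- subject records: ages uniform over 13.00-21.83 y, anthropometrics as
  linear-plus-noise growth curves that plateau at closure, and ossification
  stages derived by thresholding the relative gap width (open > 50% of
  maximum -> stage 1, partially closed -> stage 2, closed -> stage 3;
  `skj` is their sum). Sagittal-style cohorts omit stages and
  anthropometrics, mirroring cohorts for which such data was never
  collected.

Defaults emulate the target acquisition conditions: 512 x 512 x 32 grids,
in-plane spacing drawn from 0.29-0.49 mm, slice spacing 2.2-5.2 mm. The
in-plane range is the upper part of the printed 0.17-0.49 mm interval so
that the field of view always covers the 130 mm VOI plus the phantom
anatomy. Closure at 19 y reflects the male knee; the linear gap law is the
simplest monotone choice that makes parameter-recovery tests sharp.

What the phantoms do *not* emulate: realistic knee geometry, Rician
magnitude noise (Gaussian is used), scanner/protocol variation beyond
resolution, partial-volume texture, or real staging criteria. Passing
tests therefore demonstrates that the pipeline recovers a monotone
growth-plate signal under nuisance transformations — not clinical
performance.

## Numerical and design choices

- **Correlation measure**: zero-normalized cross-correlation, invariant to
  the linear intensity changes that survive bias correction. Ties break
  toward the first placement in row-major order. Patches are defined at a
  reference spacing and resampled to the image spacing before matching.
- **130 mm semantics**: read as the full side length of the crop centred
  on the match point; out-of-bounds regions are zero-padded so shapes are
  always exact, and in-bounds intensities are copied without interpolation.
- **Bias correction**: a polynomial (order 2 by default) is fitted to log
  intensities of foreground voxels by least squares and divided out,
  preserving the foreground mean. The contract is algorithm-agnostic —
  reduce smooth multiplicative non-uniformity without inflating foreground
  variation — and is enforced by property tests (coefficient of variation
  must not increase; the recovered field must correlate r > 0.9 with a
  known synthetic field).
- **Resampling**: area-overlap (box) averaging for all downsampling
  (512 -> 448, crop -> 224); it is anti-aliasing and preserves the mean
  exactly. Upsampling degenerates to piecewise-constant replication.
- **Constant slices** normalize to all zeros with a warning (the standard
  score is undefined).
- **Reduction 2 rule** (the sketch made concrete): survivors are indexed
  1..m; the survivor nearest the fraction-weighted centre of gravity
  (ties: lower index) anchors an equally spaced grid of 12 sample points
  with spacing (m-1)/11; points are rounded half-up, clamped, and
  collisions move to the nearest unused survivor, lower first. Fewer than
  12 survivors is a hard error — padding would unbalance the per-subject
  data budget.
- **Stratification** uses 1-year age bins; for fold building, adjacent
  bins are merged until each holds at least k subjects. Fold partitions
  are fixed across repeats; repeats change only the derived training
  seeds. The training split always contains the youngest and oldest
  subjects so the regressor never extrapolates.
- **95% confidence intervals** use the normal approximation
  mean ± 1.96 sd/sqrt(n) over absolute errors.
- **Head-bias initialization**: the age network's output bias starts at
  the training-mean age, i.e. exactly the best-available-guess constant.
  With Adam each parameter moves by roughly the learning rate per step, so
  a zero-initialized output cannot traverse the 13-22 y range under a
  short budget; starting at the baseline spends the budget on learning
  deviations. For budgets under 100 epochs the pipeline uses Adam's
  default step size 1e-3; the reduced 1e-4 rate is the right choice for
  the full 1000-epoch transfer-learning schedule.
- **Desk scale**: `pipeline_config(desk_scale = TRUE)` switches to
  96-voxel phantoms at ~1.5 mm spacing, 64 px network inputs with three
  blocks of base width 8, and short budgets (6 segmentation epochs, 10 age
  epochs, one CV repeat). The test suite runs entirely at this scale with
  cohorts of 8-60 subjects; the full geometry is exercised for
  construction, shape and parameter-count checks.
- **Determinism**: every stochastic operation takes an explicit seed;
  cohorts, fold plans, training runs and whole pipeline reports are
  bit-reproducible under a fixed configuration, which the tests assert.

## Known limitations

- The phantom's simplicity means segmentation is nearly saturated (Dice
  well above 0.9 is easy); the segmentation tests are contracts and sanity
  checks, not benchmarks.
- The aggregators' hyperparameters (500 trees, unlimited depth) follow
  ensemble folklore rather than a reported configuration; they are
  exposed in `aggregator_spec()`.
- Mixed availability of subject-related data is rejected rather than
  imputed; a cohort either has the full record block or none of it.
- The classifier threshold defaults to 0.5 and is exposed in
  `predict_minor()`; raising it trades sensitivity for specificity, and
  the test suite asserts the monotone direction of that trade only.
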