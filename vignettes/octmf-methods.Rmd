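---
title: "Multi-frame OCT B-scan enhancement: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-frame OCT B-scan enhancement: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A spectral-domain OCT scanner can acquire tens of B-scans of the same
retinal location in a few seconds.  Each frame shows the same anatomy under
independent speckle — the granular multiplicative noise intrinsic to
coherent imaging — plus sensor noise and small rigid displacements from eye
motion.  The traditional enhancement route registers the frames to a
reference and averages them pixel-wise (`Avg-k` for `k` frames); image
quality improves roughly with the square root of the frame count, at the
cost of scan time and patient cooperation.  The alternative implemented here
feeds a small number of aligned frames to a convolutional network trained to
reproduce a gold-standard image, aiming to reach a given quality with fewer
frames.

`octmf` implements both routes end-to-end together with the assessment
protocol used to compare them (SSIM, PSNR, paired-ROI CNR over six retinal
layer pairs, weighted Cohen's kappa for rater agreement), and a synthetic
layered-retina phantom generator that supplies ground truth for every stage.

## The phantom

Clinical multi-frame OCT data with raw repeated frames is rarely shareable,
so the package ships a generator (`make_phantom()`, `acquire_frames()`)
whose output has the statistical structure the enhancement methods rely on:

* a noise-free scene `clean` in `[0,1]`: ten tissue classes (background,
  IPL, INL, OPL, ONL, ELM, IS-OS, Inner-RPE, Outer-RPE, choroid) stacked
  with smooth low-order-polynomial boundaries, a foveal dip, low-frequency
  reflectivity texture, choroidal vessels and vessel shadows.  Per-class
  mean reflectivities are fixed defaults chosen so every high-reflection
  class (IPL, OPL, ELM, IS-OS, Outer-RPE, choroid) is brighter than its
  paired low-reflection class, making all six CNR pairs well-defined and
  positive on the clean image.  Reflectivities stay within `[0.10, 0.85]`
  so that additive noise rarely clips at the `[0,1]` range boundaries;
* per-frame rigid motion (translation + rotation about the image center),
  drawn uniformly within a configurable scale, with the reference frame kept
  at the identity.  Motion is rigid because a full repeat acquisition takes
  a fraction of a second per frame, over which eye movement is well
  approximated as uniform displacement;
* unit-mean Gamma-distributed multiplicative speckle (shape parameter
  `speckle_shape`, default 8 — a moderately noisy display-domain B-scan;
  `Inf` disables speckle) and additive Gaussian sensor noise (`sensor_sigma`,
  default 0.02).  The Gamma model is a standard coherent-imaging
  approximation; no attempt is made to calibrate it to any particular
  scanner;
* optional fixation loss: with probability `p_fixation_loss` a frame is
  replaced by a decorrelated speckled flat field, emulating a blink or
  saccade that destroys the correlation with the reference.

Everything is deterministic given a seed; the true motions and loss indices
are recorded so registration and exclusion can be graded against ground
truth.  What the phantom deliberately does *not* model: the axial
point-spread function and A-scan interferometry, vendor-specific intensity
transforms, depth-dependent signal roll-off, and pathology beyond simple
ellipsoidal hypo-/hyper-reflective lesions.  Results on phantoms therefore
demonstrate the *mechanics* of the pipeline (registration accuracy, the
averaging law, the network's advantage over averaging under this noise
model), not clinical image quality.

## Traditional path: registration and averaging

`enhance_by_averaging()` composes four stages:

1. **Reference selection** (`select_reference()`): the frame with the
   strongest SNR estimate, defined as mean tissue intensity over the
   standard deviation of background intensity, with tissue/background split
   by Otsu thresholding of each frame.  A constant frame (zero background
   spread) is treated as infinite SNR; ties break to the lowest index.
2. **Rigid registration** (`register_rigid()`): maximizes the mutual
   information (MI) of a 32-bin joint histogram between the warped moving
   frame and the reference.
3. **Exclusion** (`exclude_poor_fixation()`): a registered frame is dropped
   when its normalized correlation with the reference falls below 70% of
   the reference's zero-lag normalized autocorrelation.  Since the
   normalized zero-lag autocorrelation is identically 1, the rule reads
   "correlation < 0.70"; this is the only interpretation that yields a
   scale-free threshold, and the reference itself is never excluded.
4. **Averaging** (`average_frames()`): the pixel-wise mean of the first `k`
   surviving frames in acquisition order (how the original `Avg-k` subsets
   were chosen is not documented; acquisition order is the reproducible
   choice).

### Numerical choices in the registration

Two artifacts make "optimize interpolated MI with a simplex" — the obvious
design — unreliable on speckled frames, and both were observed directly on
phantom stacks:

* **Interpolation smoothing**: a bilinear warp at a half-pixel offset
  low-pass filters the image; since speckle is high-frequency, *any*
  half-pixel warp raises the similarity to *any* reference.  The MI surface
  acquires a 1-pixel-period oscillation whose local optima have nothing to
  do with alignment.
* **Small-sample bias**: histogram MI estimated from `N` pixels is biased
  upward by a term that grows as `N` shrinks.  If candidate shifts are
  scored on their shrinking overlap region, the surface tilts outward and
  the recovered shift systematically overshoots (about 10% of the true
  shift in our measurements).

`register_rigid()` therefore (a) Gaussian pre-smooths both images
(`smooth_sigma = 1` px), (b) always scores candidates on a *fixed central
window* of constant pixel count (margin `max_shift + 1`), and (c) searches
on the integer lattice — an exhaustive translation grid per coarse rotation
step, then a fine rotation scan at 0.1 degrees — finishing with parabolic
interpolation of the discrete MI peak, which needs no image interpolation at
all for the translation axes.  The result is deterministic, and on
default-noise phantoms recovers random perturbations up to 10 px / 3
degrees with median errors well under 0.1 px (dy), 0.35 px (dx, the axis
with less anatomical structure) and 0.1 degrees.

## The enhancement network

`build_network()` constructs a compact U-net-style model operating on `k`
input frames as channels (`k` in 1–20; one model per `k`, since the input
channel count is baked into the first convolution):

* encoder: two contracting blocks (3x3 convolutions + ReLU, 2x2 mean
  pooling), widths `C` and `2C` (`base_channels` `C = 8` by default);
* a high-resolution representation stage: two parallel branches at 1/4 and
  1/8 resolution exchanging information through repeated cross-resolution
  fusions (upsampled coarse features added into the fine branch and vice
  versa; 2 fusions by default, the final fusion feeding only the fine
  branch);
* decoder: two expanding blocks (nearest-neighbor upsampling + 3x3
  convolution + ReLU);
* a side path concatenating the two decoder resolutions at full resolution
  before the 1-channel projection head with a sigmoid;
* residual output `y = w * mean(frames) + (1 - w) * decoded`, with
  `w = sigmoid(a)` a learnable scalar initialized at 0.5 (a fixed-`w` mode
  exists for testing; `w = 1` reduces the network exactly to frame
  averaging).

The model is implemented directly in R: convolutions are evaluated as BLAS
matrix products against im2col matrices, and the backward pass is derived
by hand (the adjoint of a zero-padded 3x3 convolution is a 3x3 convolution
with the flipped kernel).  Gradients are verified against finite
differences in the test suite.  With about 18k parameters this is a
deliberately small network; the high-resolution stage is a two-branch
miniature of the full multi-branch architecture family it represents.

### Training

`train_network()` follows a conventional recipe: Xavier initialization,
Adam at an initial learning rate of 0.001, and a plateau rule that
multiplies the learning rate by 0.9 whenever the monitored training loss
fails to improve for 10 consecutive epochs (validation-loss monitoring is a
config choice away, but training loss is the default since nothing in the
recipe depends on early stopping).  The loss is

```
L = w_ce * BCE(y, target) + w_ssim * (1 - SSIM(y, target))
```

with pixel-wise binary cross-entropy over `[0,1]` intensities — the
standard reading of "cross-entropy" for image-to-image regression — and the
same Gaussian-window SSIM the assessment uses, so the loss decomposes
exactly into the reported metric.  The mixing weights default to `(1, 1)`.
Offline augmentation draws `augmentation_draws` random `k`-subsets of each
stack's surviving frames.  Since SSIM enters the loss, its gradient with
respect to the prediction is computed analytically (the adjoint of the
Gaussian windowing operator applied to the partial derivatives of the SSIM
map).

On phantoms the training target is the *clean* image: the usual clinical
gold standard (`Avg-50`) exists only because no clean image exists in vivo,
and the phantom makes the true scene available.  A config switch
(`experiment_config(target = "avg50")`) restores the Avg-50-style target
for experiments that want to mimic the clinical setup exactly.

### Desk-scale study conditions

The default experiment configuration trains one `k = 5` model on 100
phantom stacks of 128 x 256 px (8 aligned frames each, one augmentation
draw, batch size 2) for 8 epochs — a few minutes of CPU time — and
evaluates on 20 held-out phantoms.  These sizes are the package's reference
conditions for the comparison experiments; they are deliberately modest, and
every one of them is configurable upward.  Under these conditions the
trained network beats `Avg-5` by a wide margin (mean SSIM ≈ 0.89 vs ≈ 0.68
and PSNR ≈ +6 dB over 20 held-out phantoms; `scripts/acceptance.R`
recomputes the exact numbers), and raises every layer-pair CNR above the
single frame.

Fixed channel counts mean the architecture is fully convolutional: any
height/width divisible by 8 works at both training and inference.  Frame
order sensitivity: with identical input frames the output is trivially
order-invariant; with distinct frames the channels are not symmetrized, so
feeding frames in a different order can change the output — frames are fed
in acquisition order, matching how the model was trained.

## Assessment protocol

* **SSIM** (`ssim()`): mean local SSIM over 11-px Gaussian-weighted windows
  (sigma 1.5) with the standard stabilizers `c1 = 0.01^2`, `c2 = 0.03^2` on
  data range 1.  Border windows are renormalized rather than cropped, so
  `ssim(x, x) = 1` holds exactly for every image size; the implementation
  is verified against a brute-force per-window oracle in the tests.
* **PSNR** (`psnr()`): `10 log10(1 / MSE)` on data range 1, with an `Inf`
  sentinel at zero MSE.  Data range is fixed at 1 because all images are
  normalized, which keeps PSNR comparable across methods.
* **CNR** (`cnr()`): `(h - l) / sqrt(var_h + var_l)` over pooled pixels of
  paired 4 x 4-px ROIs in a high- and a low-reflection layer; six pairs
  (IPL/INL, OPL/ONL, ELM/ONL, IS-OS/Inner-RPE, Outer-RPE/Inner-RPE,
  choroid/background).  Variances are population variances, which makes the
  statistic exactly invariant under positive affine intensity maps.
  `auto_rois()` places 50 label-pure window pairs per layer at equal
  horizontal intervals using the phantom's true label map — an automated
  stand-in for manual marking that removes observer variance.
* **Weighted Cohen's kappa** (`weighted_kappa()`): chance-corrected ordinal
  agreement with quadratic (default) or linear disagreement weights.  For
  panels of more than two raters the pairwise kappas are averaged
  (`weighted_kappa_panel()` reports both schemes); the aggregation rule for
  multi-rater clinical panels is not standardized, so both the rule and the
  weight scheme are explicit options.

## Experiments

`run_sweep()` reproduces the frame-count sweep: for `k` in a chosen set it
evaluates `Avg-k` and `DL-k` (one model trained per `k`, on a disjoint
phantom split) against the clean ground truth and aggregates means and
standard deviations over replicates.  `head_to_head()` runs the paired
`DL-k` vs `Avg-k` comparison with per-phantom paired differences, a paired
t-test (marked `NA` when undefined — fewer than two phantoms or identical
outputs), and the six-pair CNR table for the single frame, `Avg-k` and
`DL-k`.  On additive-noise phantoms the averaging sweep reproduces the
analytic law `PSNR(k) - PSNR(1) = 10 log10 k` — the closed-form oracle used
throughout the tests — and under default speckle the SSIM-vs-k curve rises
monotonically with its steepest gains below five frames.

## Degenerate inputs and edge cases

* Constant images: MI is undefined (error naming the input); SNR of a
  constant frame is an infinite sentinel; CNR with two zero-variance ROI
  sets errors rather than dividing by zero.
* `PSNR = Inf` flags identical images; downstream aggregation keeps the
  sentinel.
* Exclusion at threshold 1.0 retains only exact copies of the reference
  (with a 1e-12 floating-point guard so a bit-identical frame always
  attains the bound).
* Warps fill out-of-bounds pixels with the background reflectivity (0.10),
  avoiding spurious edges that would contaminate CNR ROIs near the image
  border.
* Image sizes must be multiples of 8 for the network (two poolings plus the
  1/8-resolution branch); other sizes error with that message rather than
  silently resizing.

## Known limitations

* The Gamma speckle field is spatially white; real OCT speckle has spatial
  correlation set by the imaging PSF.  White speckle is the harder case for
  the averaging baseline and the easier case for a learned smoother, so the
  absolute DL-vs-averaging gap on phantoms should not be read as a clinical
  effect size.
* The network is trained per frame count `k`; no weight sharing across `k`.
* Registration assumes rigid motion only, which covers a single fast
  repeat acquisition but not slow drift or deformation.
* The CLI writes stack containers as RDS (R's native serialization) with a
  JSON parameter sidecar rather than HDF5.
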