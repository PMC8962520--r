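# octmf — multi-frame enhancement and quality assessment of retinal OCT B-scans

Repeated OCT B-scans of the same retinal location show identical anatomy
under independent speckle noise. `octmf` implements the two standard routes
from a stack of such frames to one enhanced image, plus the machinery to
compare them quantitatively:

* **Traditional averaging (`Avg-k`)** — reference selection by
  signal-to-noise ratio, rigid registration by mutual-information
  maximization, exclusion of poorly fixated frames (correlation below 70%
  of the reference autocorrelation), and pixel-wise averaging of `k`
  aligned frames.
* **Learned enhancement (`DL-k`)** — a compact convolutional
  encoder–decoder with a high-resolution representation stage (parallel
  multi-resolution branches with repeated cross-resolution fusion), a side
  path across decoder resolutions, and a residual output
  `y = w·mean(frames) + (1−w)·decoded`, trained with Adam on the combined
  loss `w_ce·BCE + w_ssim·(1 − SSIM)`. The network and its
  backpropagation are implemented directly on BLAS matrix products; no
  external deep-learning framework is required.
* **Assessment** — SSIM and PSNR against a gold standard; paired-ROI
  contrast-to-noise ratio `CNR = (h − l)/√(δh² + δl²)` over six retinal
  layer pairs (IPL/INL, OPL/ONL, ELM/ONL, IS-OS/Inner-RPE,
  Outer-RPE/Inner-RPE, choroid/background) from 4×4-px windows; weighted
  Cohen's kappa for ordinal rater agreement.
* **Synthetic phantom** — a layered-retina generator (ten tissue classes,
  rigid per-frame eye motion, unit-mean Gamma speckle, additive sensor
  noise, optional fixation loss and lesions) with full ground truth, so
  every stage is testable without clinical data.

See `vignettes/octmf-methods.Rmd` for the models, parameter choices and
numerical details.

## Worked example

Simulate an acquisition, enhance by averaging, and measure quality:

```r
library(octmf)

truth <- make_phantom(128, 256, seed = 5)           # clean scene + labels
acq   <- acquire_frames(truth, n_frames = 10,       # 10 speckled frames with
                        motion_scale = c(4, 1), seed = 9)   # rigid eye motion

out <- enhance_by_averaging(acq$stack, k = 5)       # register + exclude + Avg-5

# the enhanced image lives in the geometry of the SNR-selected reference
# frame; put the clean scene into that geometry before comparing
ref  <- out$registration$reference_index
gold <- warp_bscan(truth$clean, acq$truth$motions[[ref]])

ssim(acq$stack$frames[[ref]], gold)                 # single frame
#> [1] 0.3658469
ssim(out$image, gold)                               # Avg-5
#> [1] 0.7731022
psnr(acq$stack$frames[[ref]], gold)                 # dB
#> [1] 17.34843
psnr(out$image, gold)
#> [1] 26.371
```

Registering and averaging five frames lifts SSIM against the clean scene
from 0.37 to 0.77 and PSNR by 9 dB. The layer-pair contrast behaves the
same way (here on a motion-free stack so the label map applies directly):

```r
al <- acquire_frames(truth, 5, motion_scale = c(0, 0), seed = 10)
round(cnr_all_pairs(al$stack$frames[[1]], truth$layer_map), 2)   # single
#>             IPL/INL             OPL/ONL             ELM/ONL     IS-OS/Inner-RPE
#>                1.13                1.64                1.64                1.14
#> Outer-RPE/Inner-RPE  choroid/background
#>                1.26                1.78
round(cnr_all_pairs(average_frames(al$stack), truth$layer_map), 2)  # Avg-5
#>             IPL/INL             OPL/ONL             ELM/ONL     IS-OS/Inner-RPE
#>                2.32                3.27                2.93                1.96
#> Outer-RPE/Inner-RPE  choroid/background
#>                2.20                2.66
```

Training the network takes a few minutes of CPU and beats `Avg-5` at the
same frame count:

```r
cfg <- experiment_config()            # 128x256, 100 training phantoms, k = 5
rep <- head_to_head(k = 5, n_phantoms = 20, cfg = cfg, seed = 41)
rep
#> <head_to_head k=5, n=20>
#>   SSIM  Avg-5 0.6782 +/- 0.0030 | DL-5 0.8903 +/- 0.0019 (p=3.01e-39)
#>   PSNR  Avg-5 24.13 +/- 0.07 dB | DL-5 30.22 +/- 0.10 dB (p=1.44e-36)
round(rep$cnr, 2)
#>                     single  avg   dl
#> IPL/INL               1.14 2.30 3.81
#> OPL/ONL               1.72 3.42 5.38
#> ELM/ONL               1.66 2.89 3.62
#> IS-OS/Inner-RPE       1.14 1.99 2.56
#> Outer-RPE/Inner-RPE   1.31 2.24 2.87
#> choroid/background    1.78 2.73 3.11
```

At the same frame count the trained network clearly outperforms averaging
on every metric, and both enhance every layer pair's CNR over the single
frame — the qualitative ordering the method is built to deliver.

`run_sweep()` produces the full metric-vs-frame-count table for both
methods, and `weighted_kappa()` / `weighted_kappa_panel()` score ordinal
rater agreement from a score matrix.

A command-line interface wrapping these functions (subcommands `simulate`,
`register`, `average`, `train`, `enhance`, `evaluate`, `sweep`) is
installed at `system.file("scripts", "octmf.R", package = "octmf")`.

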