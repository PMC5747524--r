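# casparkle

Simulation and detection of Ca²⁺ "sparkles" in ratiometric two-photon
imaging of motile T cells.

## The problem

Ratiometric genetically encoded Ca²⁺ indicators of the Salsa6f type pair a
Ca²⁺-sensitive green fluorophore (GCaMP6f) with a Ca²⁺-insensitive red one
(tdTomato) in a single protein. In two-photon movies of T cells migrating
through lymph nodes, the red channel tracks cell position and shape while
the green channel additionally reports cytosolic Ca²⁺. Exploiting their
one-to-one correspondence, movement-driven green fluctuations can be
predicted from the red channel and subtracted, leaving a residual in which
brief subcellular Ca²⁺ transients ("sparkles", ≈2 µm², 1–2 frames) and
cell-wide transients are detected by thresholds expressed in units of the
background noise SD:

* green signal = median-filtered, z-max-projected green − 0.2 × red −
  temporal mean, within an autofluorescence mask (Bernsen local
  thresholding of temporal averages, dilated 4 px, plus manual exclusions);
* local events at ≥ 5.4 SD and ≥ 1.4 µm²; cell-wide events at ≥ 2.1 SD and
  ≥ 25 µm²; local events coinciding with cell-wide events are excluded;
* indicator calibration against a fura-2 reference (in-situ K_d ≈ 225 nM)
  via the four-parameter Hill equation
  R(ca) = R_min + (R_max − R_min)·ca^n / (K_d^n + ca^n);
* front/back subcellular comparison of per-pixel G/R ratios with a
  Mann–Whitney test.

The package is aimed at imaging groups who want this workflow as tested,
scriptable code rather than an ad-hoc macro chain — plus a seeded synthetic
movie generator with ground truth, so detection performance is measurable.

## Worked example

Fit the four-parameter Hill equation to a pooled synthetic calibration
(47 replicate curves, 8 Ca²⁺ levels, 5% multiplicative noise, generated
from the steady-state Salsa6f parameters K_d = 301 nM, n = 1.49):

```r
library(casparkle)
set.seed(1)
ca  <- c(50, 100, 150, 225, 300, 450, 900, 2000)
pts <- do.call(rbind, lapply(1:47, function(r)
  data.frame(ca_nM = ca,
             ratio = hill_ratio(ca, salsa6f_hill("steady")) *
                       (1 + 0.05 * rnorm(8)))))
fit <- fit_hill(pts)
fit
#> Four-parameter Hill fit
#>   Kd = 305.1 +/- 3.9 nM, n = 1.48 +/- 0.036
#>   Rmin = 0.001512, Rmax = 1.007, RSS = 0.272, 376 points
```

The fitted K_d (305 nM) and Hill coefficient (1.48) land on the generating
values within one standard error; `invert_hill()` then reads Ca²⁺
concentrations off the fitted curve from observed G/R ratios. The analytic
false-positive rate at the mean sparkle amplitude of 6.5 SD is

```r
background_rate(6.5)
#> [1] 2.49e+10      # one suprathreshold pixel expected per ~2 x 10^10
```

Run the whole pipeline (simulate → preprocess → detect → summarise) on the
bundled noise-free demo scene:

```r
res <- run_pipeline("all", system.file("extdata/demo_config.yaml",
                                       package = "casparkle"))
#> [casparkle] detect: stack SD = 22.59; area thresholds 3 px (local) / 54 px (cell-wide) at 0.684 um/px
#> [casparkle] detect: 5 local, 1 cell-wide, 0 excluded
summarize_events(res$events)
#> Event summary
#>   counts         : local 5, cell-wide 1, excluded 0
#>   rel. frequency : local 0.83 / cell-wide 0.17
#>   median local area : 1.87 um^2
#>   mean amplitude    : 20 SD
```

All five ground-truth sparkles are recovered, each at the 4-pixel
(1.87 µm²) area expected for a 2×2-pixel event at 0.684 µm/px, alongside
the one cell-wide transient. The same stages are available from a shell via
the thin wrapper `inst/cli/casparkle`:

```sh
Rscript inst/cli/casparkle all --config inst/extdata/demo_config.yaml
```

Noisy, full-session benchmarks come from `sparkle_benchmark_scene()`
(300 frames, 5 motile cells, 60 seeded 2×2-pixel sparkles with calibrated
6–8 SD amplitudes); `event_match_stats()` scores detections against ground
truth by spatiotemporal footprint overlap.

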