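---
title: "Models and methods behind casparkle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind casparkle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casparkle)
```

# The measurement problem

Genetically encoded ratiometric Ca^2+^ indicators of the Salsa6f type fuse a
Ca^2+^-sensitive green fluorophore (GCaMP6f) to a Ca^2+^-insensitive red one
(tdTomato). In two-photon movies of motile T cells the red channel reports
where cell label is; the green channel reports where label is *and* how much
Ca^2+^ it sees. Because the two travel together, green fluctuations caused by
cell movement, shape change or focus drift can be predicted from the red
channel and removed, leaving a residual green signal in which brief,
micron-scale Ca^2+^ transients ("sparkles") and cell-wide transients stand
out against a noise floor whose standard deviation sets the detection
thresholds.

`casparkle` implements that workflow end to end: a seeded synthetic movie
generator with ground truth, the image-conditioning chain, SD/area-threshold
event detection and classification, four-parameter Hill calibration of the
indicator against a fura-2 reference, and front/back polarity comparison of
ratiometric images.

# The indicator model

All green-channel physics runs through the four-parameter Hill equation

$$R(\mathrm{ca}) = R_\min + (R_\max - R_\min)\,
  \frac{\mathrm{ca}^{\,n}}{K_d^{\,n} + \mathrm{ca}^{\,n}},$$

with dissociation constant $K_d$ (nM), Hill coefficient $n$, and response
floor/ceiling $R_\min, R_\max$. Two in-situ parameterisations ship as
`salsa6f_hill()`: the steady-state calibration ($K_d = 301$ nM, $n = 1.49$)
and the peak-response calibration ($K_d = 162$ nM, $n = 0.93$), both on
ratios normalised to $[0, 1]$. The reference conversion from a normalised
fura-2 ratio uses the single-site form $\mathrm{ca} = K_d\, r/(1-r)$ with
$K_d = 225$ nM; the scaling factor of the classical two-wavelength equation
is absorbed by the $R_\min = 0$, $R_\max = 1$ normalisation, so no separate
$S_f/S_b$ term is modelled. FRET between the two fluorophores is not
modelled either: the red signal is treated as strictly Ca^2+^-independent.

`fit_hill()` estimates all four parameters by Levenberg--Marquardt least
squares (positivity enforced on $K_d$ and $n$ by box constraints,
`ftol = ptol = 1e-10`), with standard errors from the local curvature.
Starting values are taken from the data: extrema for $R_\min/R_\max$, the Ca
level whose ratio is nearest mid-range for $K_d$, and $n = 1$. Whether the
original calibration pooled single-cell points or fitted an averaged trace
is not knowable from the published material; the fitter accepts whatever
point set it is given, and the package's own calibration procedure pools
single-cell steady-state points. "Peak" extraction, where used, means the
maximum response to each solution step — exposed as an option, not asserted
as the published procedure.

# The synthetic movie generator

The generator exists so that every downstream stage has ground truth. It
emulates, at desk scale, two-photon lymph-node recordings: fields of view up
to 250 µm at 0.684 (or 0.488) µm/pixel, six optical sections 4 µm apart, one
stack every 5 s.

**Geometry.** Cells are spheres (default radius 4.5 µm) intersected with the
z-planes; no point-spread function or z-blur is modelled, because the
analysis chain consumes maximum-intensity projections and the detection
thresholds are calibrated empirically on rendered movies. The nucleus
(default half the cell radius) carries only a fraction (default 0.2) of the
label density — the nuclear exclusion that makes real Salsa6f cells look
dim-centred.

**Channels.** Noiseless red is `red_brightness × label density`. Noiseless
green is `red / 5 × f(ca)/f(baseline)` with `f` the Hill occupancy, so the
resting red:green ratio is exactly 5:1 — the measured resting ratio that
motivates the 0.2× red subtraction — and the red channel never depends on the
Ca^2+^ timeline. Autofluorescent objects add equal (configurable) brightness
to both channels and may drift slowly.

**Motility.** Cell velocity follows a 2-D Ornstein--Uhlenbeck process with
persistence time $P$ (default 60 s) and stationary RMS speed $v$ (default
10 µm/min, T-cell scale). Positions use the exact integrated-OU update, so
sampled paths reproduce the persistent-random-walk mean squared
displacement $\mathrm{MSD}(t) = 2 v^2 P\,(t - P(1 - e^{-t/P}))$ with no
time-step bias; paths reflect at the field boundary.

**Events.** A local event is a pixel block (default 2×2, ≈2 µm² at
0.684 µm/px) riding at a fixed offset from the cell centroid for 1–2 frames;
a cell-wide event raises the whole cytosol. Concurrent events compose by
per-pixel maximum — simpler than summation and bounded by the indicator's
dynamic range. The biological amplitude of sparkles in Ca^2+^ units is not
established; `peak_ca_nM` is therefore a free parameter, and the benchmark
scenes set it indirectly via amplitude calibration (below).

**Noise.** Shot noise is `Poisson(photon_scale × I)/photon_scale`, read
noise additive Gaussian, and a uniform `background_counts` offset (default
100 in the ready-made scenes) is added to both channels before noise.
The offset matters more than it looks: without it the Gaussian noise floor
is clipped at zero, which halves the apparent stack SD and inflates the
false-positive rate of the 5.4 SD threshold by orders of magnitude. Real
detectors have offsets; the simulated ones do too.

**What the generator does not emulate** — optical blur and scattering,
depth-dependent attenuation, second-harmonic collagen, bleaching,
chemotaxis, lymph-node architecture. Tests passing on synthetic movies
therefore demonstrate the correctness of the *pipeline arithmetic* and its
detection behaviour under the stated noise model, not performance on real
tissue.

# The preprocessing chain

Order is load-bearing and recorded in the output provenance:

1. **Median filter** each z-plane of both channels, radius 1, mirror-padded.
2. **Maximum-intensity projection** over z, per frame.
3. **Analysis mask**: temporal averages of both projected channels →
   Bernsen local thresholding (radius 5) → union over channels → dilation by
   4 px → union with declarative manual exclusion regions (boxes or
   polygons) → complement.
4. **Scaled red subtraction**: `green − 0.2 × red`, unclipped.
5. **Temporal-mean subtraction**, per pixel, of the red-subtracted stack.

The signed, zero-mean result is what the SD thresholds assume; nothing is
clipped before the stack SD is measured.

**Median element.** At radius 1 the package defaults to the 5-pixel disc
(cross), not the 9-pixel square. The difference is not cosmetic: any feature
supported on a 2×2-pixel footprint presents at most 4 high samples in every
3×3 window, so a 9-pixel median *erases minimal sparkles entirely*, and with
them the point of a 1.4 µm² (3-pixel) area threshold. With the cross, a 2×2
block passes 3-of-5 in every window it dominates and survives at full
amplitude. The square remains available (`median_shape = "square"`), and the
test suite pins the behavioural difference.

**Bernsen contrast.** The classical contrast default of 15 grey levels is
interpreted on an 8-bit scale and converted to native counts
(`15/255 × (2^bit_depth − 1)`, i.e. 3855 counts at 16 bit); low-contrast
neighbourhoods are background. Autofluorescent cells are the brightest
objects in these movies and clear this bar comfortably; moving T cells smear
out in the temporal average and do not.

**Temporal-mean convention.** The mean removed in step 5 is the mean of the
*red-subtracted* stack (the two subtractions commute up to a per-pixel
constant, so this choice only matters jointly with masking and estimation);
the alternative — subtracting the raw green mean — is available as
`mean_after_red_subtraction = FALSE`. The 0.2 scale itself can be
re-estimated per session by robust regression (`estimate_red_scale()`), but
the printed 0.2 is the default.

# Detection and classification

The single noise scale is the population SD of the masked processed stack
over the whole session. Per frame, suprathreshold pixels (≥ 5.4 SD for the
local pass, ≥ 2.1 SD for the cell-wide pass) form 8-connected components
(4-connectivity available); components smaller than
`ceiling(min_area_um2 / pixel_size²)` pixels are discarded — at 0.684 µm/px
the printed 1.4 µm² and 25 µm² thresholds become exactly 3 and 54 pixels.
Components in consecutive frames sharing at least one pixel merge into one
event (a one-frame gap splits events unless `gap_frames` allows bridging).
Each event reports its duration, its footprint area at the peak-amplitude
frame, its peak amplitude in SD units and its centroid in µm.

Classification: cell-wide iff peak ≥ 2.1 SD and area ≥ 25 µm²; local iff
peak ≥ 5.4 SD and area in [1.4, 25) µm²; an event satisfying both is
cell-wide (size dominates). A local event that *coincides* with a cell-wide
event — by default, shares ≥ 1 pixel in ≥ 1 frame; a frames-only rule is
configurable — is re-labelled `local_excluded` and leaves the sparkle set.

Background statistics come in two analytic readings, both exposed:
`background_rate(z) = 1/Q(z)` (pixels per expected suprathreshold pixel;
≈ 2.49 × 10^10^ at the 6.5 SD mean sparkle amplitude), and
`expected_false_pixels()`, which reports both the per-pixel expectation
`N·Q(z)` and the independence-based area-filtered bound `N·Q(z)^k` for
k-pixel components. After median filtering, neighbouring pixels are
correlated, so the independence bound is optimistic in principle; the
white-noise control in the test suite (ten 4 × 10⁶ pixel-frame pure-noise
movies) verifies empirically that the detector still fires essentially
never at the 5.4 SD / 3 px operating point.

# Amplitude calibration of benchmark scenes

The sparkle-recovery benchmark (`sparkle_benchmark_scene()`) must place
sparkle amplitudes in a prescribed SD band (default 6–8 SD) *as realised
after the processing chain*, not merely as injected counts: the median
filter and z-projection attenuate a small footprint by an amount that
depends on the whole chain. The scene builder therefore calibrates itself
the way an instrument is calibrated before an experiment: it renders a
short pilot movie with one cell and no events to measure the processed
noise SD, then an identical pilot carrying probe sparkles of known
noiseless green increment to measure the gain between injected increment
and realised per-pixel signal level, and finally inverts the Hill response
to convert the desired per-pixel amplitude into a `peak_ca_nM` per event.
The band is defined on the per-pixel (plateau) level of the footprint; the
*peak* amplitude reported for a detected event is a maximum over footprint
pixels, frames and z-planes and accordingly runs ~1–2 SD higher. Defining
the band on the footprint maximum instead would leave the lower half of the
band structurally undetectable under a 3-pixel area rule (three of the four
pixels must clear 5.4 SD, but the non-maximal pixels sit well below the
maximum), which is incompatible with requiring ≥ 0.9 recall.

# Polarity analysis

The front/back comparison makes algorithmic what is manual at the bench:
the motion vector is the normalised centroid displacement over a
configurable frame window (the published work does not state its window;
there is no canonical value), the cell footprint is split by the
perpendicular through the centroid (pixels exactly on the line go to the
front — a fixed, documented tie rule), and per-pixel G/R values of the two
halves are compared with a two-sided Mann--Whitney test. The test uses
midranks; the null distribution is enumerated exactly up to a combined
sample size of 16 (a runtime/fidelity balance; configurable) and otherwise
approximated normally with tie correction, the two-sided p doubling the
smaller tail, capped at 1. With every observation tied the variance is zero
and p is reported as 1.

# Numerical and interface conventions

* Pixel indices are 1-based `(row, col)`, the R convention; the centre of
  pixel `(r, c)` sits at `((c − 0.5)·px, (r − 0.5)·px)` µm, with x along
  columns and y along rows.
* All physical quantities in configuration files are µm / s / nM; pixel
  conversions happen inside the modules.
* Masked pixels are `NA` in the processed stack and excluded from every
  downstream statistic; intensities are arbitrary 16-bit counts, with
  `photon_scale` converting to photons only for noise synthesis.
* Area-to-pixel conversion rounds up (`ceiling`), reproducing the printed
  thresholds exactly at 0.684 µm/px.
* Movies are written as 16-bit multi-page TIFFs (pages T-major, then z)
  with a YAML sidecar carrying acquisition metadata, the ground-truth event
  table and cell tracks; per-frame footprint rasters stay in memory.
  Intensities are rounded to integer counts on write.

# Problem sizes

The shipped test-and-benchmark sizes are chosen so the whole suite runs
comfortably on a laptop: the sparkle-recovery benchmark uses a 300-frame,
128 × 128 px, 6-plane movie with 5 cells and 60 sparkles (a 25-minute
session at 5 s/stack over an 88 µm field); calibration recovery pools
47 replicate 8-point curves per fit and repeats the fit 100 times; the
white-noise control uses ten single-plane 100-frame 200 × 200 px movies
(4 × 10⁷ pixel-frames in total). Every randomised quantity is seeded.

# Known limitations

* No optical blur: synthetic sparkles are pixel-sharp, which flatters area
  recovery relative to real optics.
* No cell segmentation or tracking: per-cell event assignment exists only
  through synthetic ground truth; on real movies events are reported
  per field.
* The Mann--Whitney normal branch omits the continuity correction (so it
  cross-checks against `wilcox.test(..., correct = FALSE)`).
* Kinetics are outside the model: the Hill equation here is an equilibrium
  description, and on/off rates, temperature dependence of $K_d$, and
  FRET corrections are not modelled.
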