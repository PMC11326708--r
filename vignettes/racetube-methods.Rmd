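---
title: "Methods: race-tube densitometry and circadian period estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: race-tube densitometry and circadian period estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(racetube)
```

## The measurement model

A race tube converts time into distance: the mycelial growth front
advances at a roughly constant rate `v` (px/h after scanning), the
circadian clock gates conidiation, and each cycle deposits one dense
band. Daily pen marks at the growth front anchor pixel position to clock
time. Under the (imperfect) assumption of constant growth, a tube's
densitometry trace is a noisy quasi-periodic signal whose spatial period
`λ = τ·v` encodes the free-running period `τ`.

Every analysis in this package runs on a canonical frame: scans are
converted to greyscale (BT.601 weights 0.299/0.587/0.114 — the dominant
imaging convention; alpha channels are dropped since scans carry no
transparency) and resized to 1160x400 px with a separable Keys bicubic
kernel (a = −0.5). When downscaling, the kernel is widened by the scale
factor so detail is averaged rather than aliased; at native size the
resize is an exact identity, and pixel values are quantized
round-half-to-even to integers in [0, 255]. The fixed frame means every
window length, separation and threshold below lives in one coordinate
system. Orientation is an explicit argument, never auto-detected: the
user knows which end was inoculated.

## Tube boundary detection

Two independent detectors find the dark margins between tubes, and the
larger acceptable set of lines is presented (ties prefer the edge-based
detector; the choice is arbitrary but fixed, keeping selection
deterministic).

**Canny + line search.** Canny edge detection (Gaussian σ = 1, Sobel
gradients, non-maximum suppression, hysteresis thresholds 1 and 25 on the
0–255 scale) feeds a line search over every intercept row and integer
rise in ±5 px across the width (`max_slope`): tube margins are nearly
horizontal. A candidate line is accepted when its longest run of edge
pixels, bridging gaps of at most 3 px, reaches `min_line_length = 300 px`
(~26% of the width) — long enough that only inter-tube margins qualify.
We use this deterministic exhaustive search rather than a randomized
progressive probabilistic Hough transform: the parameter space is tiny
(400 intercepts × 11 slopes), exhaustive search is exact, and
reproducibility of boundary selection is a hard requirement here. A dark
margin produces a Canny edge on each flank, so accepted candidates within
`min_separation = 20 px` are merged by vote-weighted averaging, which
centres the final line on the margin rather than one flank.

**Vertical densitometry.** Row-mean brightness profiles of a 58 px strip
at the left edge and at the centre; local minima of prominence ≥ 5
brightness units are paired between strips when the implied slope is
within `max_slope`, and each pair is extended to a full-width line. This
detector survives scans where weak contrast starves the edge detector.

The image's top and bottom edges act as implicit boundaries, so n
detected lines can delimit n−1 or n+1 tubes; regions shorter than 15 px
are discarded as slivers. Fewer than two tube regions raises a classed
error rather than guessing.

## Densitometry and feature detection

Each tube region is reduced to a 1160-point trace: the mean brightness of
each column between its (possibly sloped) bounding lines, inset 3 px so
the dark margin pixels themselves are excluded.

Two Savitzky–Golay passes serve different features, and in each case the
lowest usable polynomial order is applied:

* **Band smoothing** — order 4, window 45 px. The window is ~half a band
  at the typical scale (22.5 h × 4.17 px/h ≈ 94 px), wide enough to
  suppress mycelial texture, narrow enough to keep band peaks. (The
  nominal mark window of 30 px is even; the filter requires odd windows,
  so 31 is used.)
* **Mark smoothing** — order 8, window 31 px, preserving the sharp pen
  notches. On a 3 px wide, 100-unit-deep notch this filter retains ~57%
  of the depth where the band filter retains far less; the surviving
  depth is what the prominence criterion works with.

**Time marks** are local minima of the mark-smoothed trace satisfying
three criteria: prominence ≥ 15 brightness units; steepest flank within
5 px of at least 3 units/px (band troughs are gentle — a 60-unit band at
λ = 94 px slopes at most ~2 units/px — so this cleanly separates pen
strokes from banding); and a 25 px suppression radius in which the
deepest minimum wins. The third criterion exists because an order-8
filter *rings*: a deep notch is flanked by ripple minima of prominence
~18–31 extending to ~21 px on synthetic packs, which pass the first two
criteria, while genuine daily marks are never closer than ~50 px at any
realistic growth rate. Detections within 15 px of either end of the trace
are discarded — the filter's endpoint fits are extrapolative and
routinely manufacture an artifact minimum at the last pixel. Marks are
detected per tube (pen strokes need not align vertically across tubes),
and the detection trace choice (the mark-smoothed, not raw, profile) is
deliberate: the same notches exist in both, but ringing and noise are
controlled.

Mark artifacts would read as low conidial density, so they are excised:
values within ±12 px of each mark are replaced by the straight line
joining the values just outside the window (overlapping windows merge;
windows clipped at a trace end hold the surviving anchor). Everything
outside the windows is untouched — that is an invariant, not an
implementation detail, and is asserted as such in the tests.

**Band peaks** are local maxima of the interpolated trace with width at
half prominence ≥ 10 px (rejecting noise spikes) and prominence ≥ 15
brightness units, with a 30 px most-prominent-wins suppression radius
and a 30 px edge margin. The prominence default sits above the residual
ripple the two filters leave around an excised mark (~9–13 units: the
12 px excision window is narrower than the band filter's ~22 px smear of
the notch) and well below genuine bands at usable contrast (≥ ~35 units
at contrast 40). We chose this over widening the excision window to
cover the smear: bridging ±23 px replaces nearly half of each
mark-to-mark interval with straight lines and measurably degrades the
spectral estimators downstream. Peaks before the first mark and after
the last are kept. Every threshold here is a function argument.

## Calibration and growth rate

With mark positions `x_i` and user times `t_i`, the growth rate in px/h
is the mean of per-interval rates `Δx_i/Δt_i` — matching the "mean rate"
wording of the assay tradition — rather than a least-squares slope (that
alternative is available via `method = "least_squares"`). Growth is not
exactly linear, which is why the per-interval mean and the global slope
differ; no nonlinearity correction is attempted. A user-measured physical
distance between the first and last marks fixes mm/px, and the growth
rate is `px_per_hour × mm_per_px`. Without a measurement the rate is
`NA` ("N/A" in exports) — never guessed. Note the correct invariance:
stretching the image rescales every pixel coordinate while the physical
measurement stays fixed, and the mm/h rate is unchanged.

## Period estimation

All four estimators run on the interpolated trace of a selected window
(any pair of marks; default the whole trace), and fail independently —
one estimator's classed error never blocks the others.

**Linear regression.** τ = mean consecutive band spacing × hours-per-px.
Needs ≥ 2 band peaks.

**Sokolove–Bushell.** For each integer candidate period P (px) in the
search band, the series is folded into K = ⌊N/P⌋ complete rows
(trailing remainder discarded) and scored

    Q_P = K · Σ_h (X̄_h − X̄)² / [ (1/(N−1)) · Σ_i (X_i − X̄)² ]

with N = K·P the folded length. This exact normalization — K and (N−1)
prefactors together — differs from some textbook chi-squared periodogram
forms; it is implemented verbatim as stated, and the test suite pins the
vectorized implementation against a literal loop transcription at
relative 1e−9.

**Lomb–Scargle.** The classical least-squares power of the mean-centred
series, with the orthogonalizing phase offset
`tan(2ωτ₀) = Σ sin(2ωt_j) / Σ cos(2ωt_j)`, evaluated on a frequency grid
covering the band with oversampling 16 (grid step `1/(16N)` cycles per
sample — fine enough that grid quantization is ~0.1 h at 22.5 h). At the
true frequency of a unit sinusoid the power approaches N/4, which the
tests verify.

**CWT.** Complex Morlet (centre frequency 1.0, bandwidth 1.5 — the
wavelet family is conventional; the centre frequency makes scale equal
period in px), 100 log-spaced scales across the band, computed by
FFT convolution. Amplitude uses **L1 scale normalization (1/a)**: with
the more common L2 (1/√a) convention, equal-amplitude sinusoids score as
√a — larger periods win spuriously, and on a pure 94 px sinusoid the
ridge mean lands ~0.4 h high, which the 75% acceptance rule then bakes
into the period. With L1 the response is scale-flat. The per-time ridge
is the period of maximal amplitude; points above 75% of the global
maximum are accepted (edge regions self-exclude because zero-padding
attenuates them); the period is the mean accepted ridge period and the
slope of the best-fit line through the accepted (time, period) points
reports drift in hours of period per hour of time. Fewer than two
accepted points yields slope 0 with a warning.

**Search band and detrending.** Spectral peaks are taken inside a
configurable circadian band, default 14–40 h: an unrestricted argmax can
land on harmonics or the near-DC growth-front trend. All three spectral
methods mean-centre; the CWT additionally removes a linear trend by
default (the bright-to-dark growth gradient otherwise leaks into the
lowest scales), while SB/LS do not (mean-centring suffices for a folded
statistic and the LS model, and Q_P is invariant to centring). Series
whose standard deviation is at numerical-noise level relative to their
magnitude (≤ 1e−8 × scale — smoothing a constant leaves ~1e−14 jitter)
raise a degenerate-series error.

## The synthetic generator

`generate_pack()` is first-class, tested code: it renders boundaries
(thin dark lines, optional vertical tilt), a linear bright-to-dark
growth gradient, raised-cosine conidial bands (smooth grading, as in
real scans — and deliberately exercising the width/prominence criteria),
per-tube jittered pen strokes, and additive Gaussian noise, then emits
exact ground truth (boundary rows, mark x/t pairs, analytic band-peak
positions). Defaults describe a realistic wild-type-like pack: 6 tubes,
τ = 22.5 h, v = 4.1667 px/h (a 24 h mark interval spans 100 px and the
frame holds ~11 days), contrast 60, noise sd 8, 1 px mark jitter.
Banding begins at the first mark (cultures synchronize at the transfer
to darkness) and the band field ends on a trough so no half-formed peak
sits at the growth front; all tubes share one band phase, as cultures
started together do.

What it does **not** emulate — and therefore what green tests do not
demonstrate about real scans: mycelial texture, growth-rate drift along
the tube (the nonlinearity the calibration section acknowledges),
tube-to-tube biological period variation, scanner vignetting, bubbles,
and condensation. In particular, synthetic tubes are near-replicas, so
between-tube SEMs are far smaller than the biological SEMs seen in real
packs; criteria phrased relative to between-tube SEM are much stricter
here than on real data.

## Problem sizes used in validation

The checks in `tests/testthat/` run at sizes chosen to exercise the
estimators well past their asymptotic behaviour while staying quick:
oracle equivalence on 50 random series of 200–1200 samples; parameter
recovery on 50 seeded packs with true periods uniform in 18–26 h at
noise sd 8; feature detection on 50 randomized packs of 3–8 tubes,
noise sd 0–10, contrast 40–80.

## Known limitations

* Bent tube ends must be cropped before upload; only the straight
  portion is modelled, and curved-tube geometry is out of scope.
* The Sokolove–Bushell candidate grid is integer px, so its period
  resolution is `hours_per_px` (~0.24 h at default scale); estimates
  quantize accordingly.
* No significance testing of periodogram peaks is provided, and no
  correction for nonlinear growth.
* Accepted input formats are those of the underlying image reader
  (PNG, TIFF, JPEG).
* The experiment file stores densitometry at 4-decimal precision (so
  round trips are byte-stable); differences below 1e−4 brightness units
  are not preserved.
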