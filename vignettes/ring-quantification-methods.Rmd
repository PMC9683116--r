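---
title: "Quantifying contractile-ring dynamics: methods and design notes"
author: "ringmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contractile-ring dynamics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmetrics)
```

## The measurement problem

During cytokinesis, an actomyosin ring assembles at the equatorial cortex of
a dividing cell and constricts to pull in the plasma membrane. Live imaging
of fluorescently tagged ring components (anillin, Ect2, RhoA) yields
time-lapse Z-stacks from which several per-cell statistics are routinely
read out:

* **peak breadth** — how far along the cortex the equatorial enrichment of a
  ring protein extends, in micrometres or as a fraction of cortical length;
* **furrow/pole enrichment** — how concentrated the protein is at the
  equator relative to the polar cortex;
* **cortex/cytosol ratio** — whether the protein is cortical at all before
  anaphase (a metaphase measurement);
* **ingression duration** — minutes from anaphase onset until the membrane
  appears fully closed;
* **closure symmetry** — whether the ring constricts concentrically or
  sweeps to one side, scored from an end-on view.

This package implements each estimator and a synthetic movie generator
that provides ground truth for all of them.

## Estimators

### Linescan profiling and normalization

A cortical profile is sampled along a user-traced pole-to-pole polyline at
1-pixel arc spacing; each sample averages five bilinear sub-samples placed
perpendicular to the local path direction (`extractCorticalLinescan()`).
Samples are positioned relative to the furrow by intersecting the traced
furrow line with the path (`registerToFurrow()`). Normalization
(`normalizeProfile()`) computes the baseline as the average of the first or
last 50 samples — the pole windows — and the peak height as the profile
maximum minus that baseline.

Because "first or last" is ambiguous when a pole abuts a neighbouring cell,
the default takes the *lower* of the two pole-window means
(`baselineMode = "min"`); pooling both windows is available as
`baselineMode = "both"`. Ties at the maximum resolve to the lowest arc
position so results are deterministic.

### Peak breadth

`peakBreadth()` counts samples at or above
`baseline + cutoff × peakHeight` within the contiguous run containing the
peak; above-cutoff samples outside that run (isolated bright pixels) are
excluded and reported separately. The cutoff is deliberately
baseline-relative, making the breadth invariant under affine intensity
transforms — gain and offset changes between imaging sessions cannot move
it. Two cutoffs are in standard use: 50% accommodates proteins with low
peak intensity (e.g. RhoA) when comparing different proteins, and 75%
compares one protein across cell lines. Samples exactly at the cutoff count
as above it; this boundary convention is stated once here and applied
everywhere.

For a Gaussian band of arc-length sigma $\sigma$, the expected breadth at
cutoff fraction $f$ is $2\sigma\sqrt{-2\ln f}$
(`gaussianBandWidthUm()`), i.e. the FWHM $2\sigma\sqrt{2\ln 2}$ at $f=0.5$.

### Enrichment ratios and their estimator bias

`furrowEnrichment()` is the mean *raw* intensity over the breadth region
divided by the pole-window mean. It is scale-invariant but **not**
offset-invariant, which is why background subtraction must precede it.

One property of this estimator deserves emphasis. For a Gaussian band of
peak fold-enrichment $F$, the mean of the band over the region above cutoff
$f$ is not $F$ but $1 + (F-1)\,\bar g_f$ with

$$\bar g_f = \frac{\sqrt{\pi/2}}{\sqrt{-2\ln f}}\,
  \operatorname{erf}\!\bigl(\sqrt{-\ln f}\bigr),$$

which is 0.810 at $f=0.5$ and 0.912 at $f=0.75$. An 8-fold band therefore
*reads* as ~6.7 when averaged over its FWHM and ~7.4 when averaged over the
75% region. This is a property of the definition, not an implementation
artifact; it is the reason the package's parameter-recovery studies (and
the acceptance script) measure enrichment at the 75% cutoff, where the
definitional bias stays within a 15% band of the generative fold. Users
comparing conditions measured with the *same* cutoff are unaffected, since
the bias factor cancels in relative comparisons.

### Ingression duration

`ingressionDuration()` takes a per-frame furrow-width trace and returns
`(closureFrame − anaphaseFrame) × frameInterval`, where closure is the
first frame whose width is at or below `closureWidthPx` (1 pixel — the
resolution limit for "membrane appears fully closed"). Cells that never
reach the threshold are flagged `not closed` and excluded from durations
rather than given a censored value. Furrow tracking itself is out of scope:
the trace comes from annotations or simulator truth.

### Ring-closure symmetry

`resliceEndOn()` resamples a rectangular region (250 × 50 px by default) so
Z becomes an in-plane axis, scaled by `zStep/pixelSize` with linear
interpolation — the closing ring is then seen face-on. Manual ring
outlines (≥ 5 perimeter points, or ellipse parameters) are fitted by direct
least-squares ellipse fitting and reduced to circles with radius
$(a+b)/2$ (`fitCircle()`; $\sqrt{ab}$ available behind
`circleRadiusRule = "geometric"`). `normalizeTrajectory()` maps the
first-frame ring to centre $(0,0)$, radius 1; the **symmetry value** is
the Euclidean distance from the origin to the *last* measured ring centre
in those units. Intermediate timepoints are plotted but do not enter the
score — only the endpoints do, as the definition states. Values below 0.2
are symmetric, above 0.6 highly asymmetric, and the boundaries 0.2 and 0.6
fall in the middle (asymmetric) class; the published wording ("less than
0.2", "between 0.2 and 0.6", "greater than 0.6") leaves the boundary
points open, so the convention is fixed here once.

The "centre of the cell in the first timepoint" is taken to equal the
first ring-fit centre, which the normalization pins to the origin.

## Preprocessing

The preprocessing defaults are parameter-free and monotone: per-frame 5th
percentile background subtraction (appropriate when most of the field of
view is background) and simple-ratio bleach correction (each frame scaled
so its mean matches frame 0). An exponential-fit correction
(`A e^{-kt}` fitted to frame means) is available where the ratio method's
frame-to-frame noise coupling matters. Background subtraction must come
first: residual background biases the frame means the bleach correction
relies on. Z-projection averages the *n* central slices, with the block
starting at `floor((Z − n)/2)` — a convention that is symmetric whenever
parities allow and deterministic otherwise. Two central slices are used
for cortical linescans, six for midzone (central-spindle) profiles.

With 5% noise the 5th percentile of the background distribution
underestimates the true background by ~1.6 standard deviations; this
residual offset propagates into enrichment ratios at the few-percent
level. It is part of the method as published-style pipelines apply it, and
the recovery studies below absorb it within their tolerance.

## The synthetic movie generator

`simulateDivisionMovie()` renders what the estimators assume: a rounded
mitotic cell as a spherical cortical shell around a cytosolic pool,
rasterized per Z slice from the voxel's 3-D radius. The equatorial band is
a Gaussian in cortical arc length; ingression constricts the boundary
within a fixed furrow zone (Gaussian of sigma 1.5 µm along the division
axis) at a constant rate; asymmetric closure drifts the constriction
centre toward one side by `closureAsymmetry × (R − ringRadius)`, reaching
`closureAsymmetry × R` at closure. Bleaching multiplies each frame by
`(1 − rate)^t`; a constant background is added; noise (gaussian, or
poisson treating the a.u. value as the expected count) is applied last. A
second chromatin-like channel is not rendered: it would be visual QC only
and is never quantified.

Default conditions: 128 × 128 px at 0.2 µm/px, 11 slices of 1 µm, 15
frames every 2 min, cell radius 10 µm, cortex thickness 1.6 µm, cytosol
120 / cortex 300 a.u., 8-fold band of sigma 2 µm from frame 1, ingression
from frame 3 at 1 µm/min, 2% bleaching per frame, background 50 a.u.,
gaussian noise sigma 10 a.u. (~3% of the cortical level). These are
realistic magnitudes for endogenously tagged ring proteins imaged on a
spinning-disk system; no attempt is made to mimic any specific cell line's
published values.

Two rendering constraints matter for interpretation:

* The shell thickness is the *apparent* (optically blurred) cortex, and it
  must exceed the linescan width plus bilinear support
  (5 px × 0.2 µm + ~0.3 µm per side ≈ 1.4 µm) for the five-pixel linescan
  to sample pure cortex; the 1.6 µm default satisfies this, and with a
  thinner shell the flat-cortex control shows percent-level rasterization
  ripple rather than a flat line.
* The equatorial band adds intensity; total fluorescence is constant over
  time only once the band is present (set `enrichmentOnsetFrame = 0` for
  strict conservation checks) and until ingression changes the geometry.

`GroundTruth` records the generative parameters in estimator units — e.g.
`trueBreadthUm` is the analytic band width at the stated cutoff, and
`trueSymmetryValue` is the normalized centre offset at the last frame
whose ring radius is still ≥ 2 px (smaller rings cannot be outlined), so a
movie truncated mid-closure has a truth consistent with what any observer
of that movie could measure. Since `SimParams` carries no separate
anaphase-onset field, `ingressionStartFrame` is the time zero of the
simulated duration truth.

What the simulator does **not** emulate: point-spread blur beyond the
effective shell thickness, depth-dependent attenuation, cell-to-cell
shape variation, neighbouring cells, cortical flows, or central-spindle
signal. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated geometry, not robustness to every property of
real movies — which is exactly what a ground-truth simulator is for.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on 12–20
simulated movies (128 × 128 × 11 × 15 voxels each, a few seconds per
movie), 1 000 random 301-sample profile fixtures for the brute-force
breadth oracle, and 100-seed Monte-Carlo loops for circle fitting and
trajectory jitter; these sizes give Monte-Carlo errors comfortably below
the tolerances being checked. All randomness is seeded; identical
parameters (including seed) produce bit-identical movies. Degenerate
inputs fail loudly: collinear outlines, empty ROIs, zero first-frame
means, profiles shorter than two pole windows, non-positive pole means and
images too small to hold the simulated cell are all rejected with
specific messages rather than propagated as NaN.

## Known limitations

* Cortex paths, furrow lines and ring outlines are inputs (manual tracing
  or simulator truth); no automated segmentation or ring detection.
* The enrichment estimator's definitional bias (above) means absolute
  fold-enrichments are conservative; cross-condition comparisons at a
  fixed cutoff are unaffected.
* `simple_ratio` bleach correction assumes the in-frame geometry changes
  slowly relative to bleaching; movies dominated by rapid shape change
  should prefer `exponential_fit`.
* Hypothesis testing beyond n/mean/SD summaries is intentionally out of
  scope; standard R tools apply directly to the tidy outputs.
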