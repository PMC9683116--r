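# ringmetrics

Quantification of contractile-ring dynamics in live-cell fluorescence
movies of dividing cells.

During cytokinesis an actomyosin ring assembles at the cell equator and
constricts to separate the daughters. Labs imaging tagged ring proteins
(anillin, Ect2, RhoA) quantify this process with a small set of per-cell
statistics, usually assembled by hand from ImageJ linescans and
spreadsheets. `ringmetrics` implements that workflow as tested, scriptable
R functions for anyone measuring furrowing cells:

* **Cortical linescan profiling** — intensity along a five-pixel-wide
  pole-to-pole path, registered to the furrow and normalized against
  50-pixel pole windows: baseline *b* = mean pole-window intensity, peak
  height *h* = max − *b*.
* **Peak breadth** — the contiguous run of samples with intensity
  ≥ *b* + *f·h* (cutoff fraction *f* = 0.5 or 0.75) containing the peak,
  in µm or as a fraction of cortical length; isolated above-cutoff pixels
  outside the run are excluded. For a Gaussian band of arc-length sigma σ
  the expected breadth is 2σ√(−2 ln *f*) (the FWHM 2σ√(2 ln 2) at
  *f* = 0.5).
* **Enrichment ratios** — mean intensity over the breadth region / pole
  mean (anaphase furrow enrichment), and cortex linescan mean / cytosol
  ROI mean (metaphase).
* **Ingression duration** — (closure frame − anaphase frame) × frame
  interval, where closure is furrow width ≤ 1 px.
* **Ring-closure symmetry** — end-on reslice, least-squares ellipse →
  best-fit circle per frame, trajectory normalized so the first ring is
  centre (0,0), radius 1; the symmetry value is ‖last centre‖ in those
  units. < 0.2 symmetric, 0.2–0.6 asymmetric, > 0.6 highly asymmetric.
* **Preprocessing** — percentile/ROI/constant background subtraction,
  simple-ratio or exponential-fit bleach correction, central-slice average
  Z-projection.
* **A synthetic dividing-cell movie generator** with full ground truth
  (band breadth, fold enrichment, ingression duration, symmetry value,
  per-frame ring geometry), so every estimator can be validated without
  external data.

See `vignettes/ring-quantification-methods.Rmd` for the estimator
definitions, simulator geometry and design decisions.

## Worked example

```r
library(ringmetrics)

# simulate a dividing cell closing asymmetrically
sim <- simulateDivisionMovie(SimParams(closureAsymmetry = 0.5, seed = 6))
movie <- sim$movie
truth <- sim$truth
movie
#> Movie [green]: T=15 Z=11 Y=128 X=128, 0.2 um/px, dz=1 um, dt=2 min
truth
#> GroundTruth: breadth 4.71 um (50% cutoff), fold 8, symmetry 0.4, ingression 10 min

# preprocess: background, bleaching, central-slice projection
pre <- correctBleaching(subtractBackground(movie, "percentile"), "simple_ratio")
planes <- projectZ(pre, 2L)

# cortical linescan at furrow onset (frame 3), registered to the furrow
fr <- 3L
path <- CortexPath(truth@cortexPath[[fr + 1]], widthPx = 5L, frameIndex = fr)
fl <- truth@furrowLine[[fr + 1]]
prof <- extractCorticalLinescan(planes, path)
prof <- registerToFurrow(prof, path, FurrowLine(fl[1, ], fl[2, ], fr))
prof <- normalizeProfile(prof)

cfg <- QuantConfig(breadthCutoffFraction = 0.75)
br <- peakBreadth(prof, cfg)
br
#> BreadthResult: 14 px = 2.8 um at 75% cutoff (0 excluded)
furrowEnrichment(prof, br)
#> EnrichmentResult: furrow/pole = 6.968 (furrow 1423, pole 204.2)

# ingression duration from the furrow-width trace
ingressionDuration(truth@furrowWidthTracePx, anaphaseFrame = 3L,
                   frameIntervalMin = 2)$durationMin
#> [1] 10

# ring-closure symmetry from per-frame ring outlines
outl <- ringOutlinesFromTruth(truth, nPoints = 10, jitterPx = 0.2, seed = 6)
fits <- lapply(names(outl), function(k) fitCircle(outl[[k]], as.integer(k)))
traj <- normalizeTrajectory(fits)
round(symmetryValue(traj), 3)
#> [1] 0.401
classifySymmetry(symmetryValue(traj))
#> [1] "asymmetric"
```

Reading the numbers: the simulated cell carries an 8-fold equatorial band
of sigma 2 µm, whose width at the 75% cutoff is 2·2·√(−2 ln 0.75) ≈
3.03 µm — the pipeline measures 2.8 µm. The enrichment ratio of 6.97
reflects the definition (a mean over the breadth region is below the
peak; an 8-fold Gaussian band averages to ~7.4 over its 75% region — see
the vignette) plus residual background. The ring, constricting with
asymmetry 0.5, had drifted 0.4 radii off-centre by the last measurable
frame, matching the ground truth of 0.4 and classifying as asymmetric.

Batch analyses run from a JSON/YAML manifest via `runPipeline()`, or from
the shell via the thin CLI at `inst/scripts/ringmetrics`
(`simulate | preprocess | linescan | metrics | symmetry | report`).

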