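Package: ringmetrics
Title: Quantification of Contractile-Ring Dynamics in Live-Cell Fluorescence Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cytokinetic contractile-ring dynamics from time-lapse
    Z-stack fluorescence movies of dividing cells. Implements cortical linescan
    intensity profiling along a five-pixel-wide pole-to-pole path, furrow
    registration and baseline normalization, equatorial peak breadth at a
    configurable cutoff fraction (50% or 75%) with isolated off-peak pixel
    exclusion, furrow-versus-pole and cortex-versus-cytosol enrichment ratios,
    ingression duration from anaphase onset to membrane closure, and end-on
    ring-closure symmetry scoring (normalized first-to-last ring-center
    displacement) with symmetric / asymmetric / highly-asymmetric
    classification. Includes background subtraction, photobleaching correction,
    and central-slice average Z-projection preprocessing, plus a synthetic
    dividing-cell movie generator with full ground truth so every stage is
    testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, grDevices, graphics, tiff, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
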