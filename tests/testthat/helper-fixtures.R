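# small, fast simulation settings shared across tests; noiseless and
# bleach-free unless a test overrides them
quietParams <- function(...) {
  args <- utils::modifyList(list(noiseModel = "none", bleachRatePerFrame = 0,
                                 backgroundLevel = 0), list(...))
  do.call(SimParams, args)
}

# independent brute-force breadth oracle: walk outward from the argmax
# while samples stay at or above the cutoff; count above-cutoff samples
# left outside that walk
bruteBreadth <- function(int, baseline, frac) {
  cutoff <- baseline + frac * (max(int) - baseline)
  pk <- which.max(int)
  lo <- pk
  while (lo - 1 >= 1 && int[lo - 1] >= cutoff) lo <- lo - 1
  hi <- pk
  while (hi + 1 <= length(int) && int[hi + 1] >= cutoff) hi <- hi + 1
  list(n = as.integer(hi - lo + 1), lo = as.integer(lo), hi = as.integer(hi),
       excluded = as.integer(sum(int >= cutoff) - (hi - lo + 1)))
}

# run the cortical-linescan half of the pipeline on simulator output and
# return the per-cell measurements at the requested cutoff
measureSimulatedCell <- function(sim, cutoff = 0.75,
                                 frame = sim$truth@params@ingressionStartFrame) {
  p <- sim$truth@params
  pre <- correctBleaching(subtractBackground(sim$movie, "percentile"),
                          "simple_ratio")
  planes <- projectZ(pre, 2L)
  path <- CortexPath(sim$truth@cortexPath[[frame + 1L]], widthPx = 5L,
                     frameIndex = frame)
  fl0 <- sim$truth@furrowLine[[frame + 1L]]
  prof <- extractCorticalLinescan(planes, path)
  prof <- registerToFurrow(prof, path, FurrowLine(fl0[1, ], fl0[2, ], frame))
  prof <- normalizeProfile(prof)
  cfg <- QuantConfig(breadthCutoffFraction = cutoff)
  br <- peakBreadth(prof, cfg)
  en <- furrowEnrichment(prof, br)
  list(profile = prof, breadth = br, enrichment = en,
       breadthUm = breadthUm(br), ratio = enrichmentRatio(en))
}
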