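# Shared fixtures, built once per test run and cached. Phantom generation
# and registration are the expensive steps; everything that needs them
# pulls from this cache so the suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixtures)) assign(name, force(expr), .fixtures)
  get(name, .fixtures)
}

# small noiseless phantom for cheap unit checks
smallPhantom <- function() fixture("smallPhantom", {
  makeCtPair(phantomSpec(gridShape = c(32, 32, 32), nHotspots = 0L,
                         noiseModel = "none", seed = 5))
})

# default-condition phantom + full pipeline (used by study and
# acceptance tests)
pipelineReport <- function() fixture("pipelineReport", {
  runPipeline(phantomSpec(seed = 11))
})

# default-condition phantom with its SPECT volume, aligned via the true
# offset and true field (isolates the tracer statistics from
# registration error)
alignedSpect <- function(seed = 11, nHotspots = 2L, hotspotAmplitude = 5,
                         noiseModel = "none", fsadFraction = 0.12) {
  key <- paste("alignedSpect", seed, nHotspots, hotspotAmplitude,
               noiseModel, fsadFraction, sep = "_")
  fixture(key, {
    spec <- phantomSpec(seed = seed, nHotspots = nHotspots,
                        hotspotAmplitude = hotspotAmplitude,
                        noiseModel = noiseModel,
                        fsadFraction = fsadFraction)
    ph <- makeCtPair(spec)
    sp <- makeSpect(spec, ph$truth, ph$lobes)
    se <- resampleToGrid(sp$spect, ph$exp,
                         transform = sp$truth@spectOffset)
    st <- applyDisplacement(se, ph$truth@displacement)
    list(spec = spec, phantom = ph, spect = sp$spect, truth = sp$truth,
         aligned = st)
  })
}

expect_within <- function(value, target, tol) {
  expect_true(abs(value - target) <= tol,
              label = sprintf("|%.4g - %.4g| <= %.4g", value, target, tol))
}
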