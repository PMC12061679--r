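test_that("a disease-free phantom classifies as fully normal lung", {
  spec <- phantomSpec(gridShape = c(32, 32, 32), fsadFraction = 0,
                      emphFraction = 0, nHotspots = 0L,
                      noiseModel = "none", seed = 3)
  ph <- makeCtPair(spec)
  ew <- applyDisplacement(ph$exp, ph$truth@displacement, fill = -1000)
  prm <- prmClassify(ph$insp, ew, ph$lobes)
  tot <- prm[prm$region == "Total", ]
  expect_equal(tot$fsadPct, 0)
  expect_equal(tot$emphPct, 0)
})

test_that("zero deformation magnitude yields an identity pair", {
  spec <- phantomSpec(gridShape = c(32, 32, 32), deformationMagnitude = 0,
                      nHotspots = 0L, noiseModel = "none", seed = 3)
  ph <- makeCtPair(spec)
  expect_equal(max(abs(imgData(ph$truth@displacement))), 0)
  expect_identical(imgData(ph$insp), imgData(ph$exp))
})

test_that("identical specifications generate bit-identical phantoms", {
  spec <- phantomSpec(gridShape = c(32, 32, 32), seed = 17)
  a <- makeCtPair(spec); b <- makeCtPair(spec)
  expect_identical(imgData(a$insp), imgData(b$insp))
  expect_identical(imgData(a$exp), imgData(b$exp))
  expect_identical(imgData(a$truth@displacement),
                   imgData(b$truth@displacement))
  sa <- makeSpect(spec, a$truth, a$lobes)
  sb <- makeSpect(spec, b$truth, b$lobes)
  expect_identical(imgData(sa$spect), imgData(sb$spect))
  expect_identical(sa$truth@spectOffset@translation,
                   sb$truth@spectOffset@translation)
})

test_that("phantom truth is internally consistent", {
  ph <- smallPhantom()
  truth <- ph$truth
  expect_equal(sum(truth@lobarVentilation), 1, tolerance = 1e-9)
  # class map nonzero exactly on the lung mask
  expect_identical(truth@classMap@data > 0L, ph$lobes@data > 0L)
  # degenerate grids are rejected outright
  expect_error(phantomSpec(gridShape = c(15, 32, 32)), ">= 16")
})

test_that("seeded class fractions are recovered within 2 points", {
  # generator self-consistency across the seeded-fraction range, using
  # the true displacement (registration error tested separately)
  for (f in list(c(0.05, 0.05), c(0.2, 0.1), c(0.4, 0.1))) {
    spec <- phantomSpec(fsadFraction = f[1], emphFraction = f[2],
                        nHotspots = 0L, noiseModel = "none", seed = 42)
    ph <- makeCtPair(spec)
    ew <- applyDisplacement(ph$exp, ph$truth@displacement, fill = -1000)
    tot <- prmClassify(ph$insp, ew, ph$lobes)
    tot <- tot[tot$region == "Total", ]
    expect_within(tot$fsadPct, 100 * f[1], 2)
    expect_within(tot$emphPct, 100 * f[2], 2)
  }
})

test_that("tissue mass is conserved between the paired volumes", {
  spec <- phantomSpec(nHotspots = 0L, noiseModel = "none", seed = 42)
  ph <- makeCtPair(spec)
  ew <- applyDisplacement(ph$exp, ph$truth@displacement, fill = -1000)
  J <- imgData(deformationMetrics(ph$truth@displacement)$jacobian)
  lung <- ph$lobes@data > 0L
  bI <- imgData(tissueFraction(ph$insp))
  bW <- imgData(tissueFraction(ew))
  ratio <- sum((J * bW)[lung]) / sum(bI[lung])
  expect_within(ratio, 1, 0.01)
})

test_that("a homogeneous tracer field has near-zero heterogeneity", {
  spec <- phantomSpec(gridShape = c(64, 64, 64), fsadFraction = 0,
                      emphFraction = 0, nHotspots = 0L,
                      noiseModel = "none", seed = 3)
  ph <- makeCtPair(spec)
  sp <- makeSpect(spec, ph$truth, ph$lobes)
  se <- resampleToGrid(sp$spect, ph$exp, transform = sp$truth@spectOffset)
  st <- applyDisplacement(se, ph$truth@displacement)
  expect_lt(cvTotal(st, ph$lobes), 0.05)
  expect_within(tcMax(st, ph$lobes), 1, 0.05)
})

test_that("hot spots raise the standardized maximum on matched seeds", {
  hot <- alignedSpect(seed = 11, nHotspots = 2L, hotspotAmplitude = 10)
  none <- alignedSpect(seed = 11, nHotspots = 0L)
  tcHot <- tcMax(hot$aligned, hot$phantom$lobes)
  tcNone <- tcMax(none$aligned, none$phantom$lobes)
  expect_gt(tcHot, tcNone)
  cvHot <- cvTotal(hot$aligned, hot$phantom$lobes)
  expect_gt(cvHot, cvTotal(none$aligned, none$phantom$lobes))
})

test_that("tracer statistics are invariant to count rescaling", {
  ax <- alignedSpect(seed = 11, nHotspots = 2L, hotspotAmplitude = 5)
  doubled <- ImageVolume(2 * imgData(ax$aligned), spacing(ax$aligned),
                         origin(ax$aligned))
  expect_equal(cvTotal(doubled, ax$phantom$lobes),
               cvTotal(ax$aligned, ax$phantom$lobes), tolerance = 1e-12)
  expect_equal(tcMax(doubled, ax$phantom$lobes),
               tcMax(ax$aligned, ax$phantom$lobes), tolerance = 1e-12)
})

test_that("lobar tracer shares track the true lobar ventilation", {
  ax <- alignedSpect(seed = 11, nHotspots = 0L)
  tcp <- tcPercent(ax$aligned, ax$phantom$lobes)
  r <- cor(as.vector(tcp) / 100, ax$truth@lobarVentilation)
  expect_gt(r, 0.7)
})

test_that("panel generator enforces admissible correlation structures", {
  expect_error(makePanelDataset(5, 0.3, seed = 1), ">= 8")
  expect_error(makePanelDataset(100, 0.3, seed = 1, sync = 1.2),
               "\\[-1, 1\\]")
  expect_error(makePanelDataset(100, 0.9, seed = 1, stabilityY = 0.9),
               "positive definite")
  d <- makePanelDataset(5000, 0.5, seed = 2)
  # realized moments close to the implied ones
  expect_within(cor(d$x1, d$y1), 0.5, 0.05)
  expect_within(cor(d$x1, d$x2), 0.6, 0.05)
  expect_within(cor(d$x1, d$y2), 0.8, 0.05)
})

test_that("phantoms write to NIfTI with a readable truth sidecar", {
  ph <- smallPhantom()
  dir <- withr::local_tempdir()
  writePhantom(ph, dir)
  expect_true(file.exists(file.path(dir, "ct_insp.nii.gz")))
  back <- readVolume(file.path(dir, "ct_insp.nii.gz"))
  expect_equal(imgData(back), imgData(ph$insp), tolerance = 1e-5)
  expect_true(file.exists(file.path(dir, "truth.csv")))
})
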