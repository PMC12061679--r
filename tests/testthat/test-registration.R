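test_that("deformation metrics match closed forms", {
  d <- c(12, 12, 12)
  idx <- expand.grid(i = 1:12, j = 1:12, k = 1:12)
  # zero field
  z <- deformationMetrics(DisplacementField(array(0, c(d, 3))))
  expect_equal(range(imgData(z$jacobian)), c(1, 1))
  expect_equal(max(imgData(z$adi)), 0)
  # uniform isotropic expansion u = (s - 1) x with s = 1.2
  u <- array(0, c(d, 3))
  w <- cbind(idx$i - 1, idx$j - 1, idx$k - 1)   # spacing 1, origin 0
  for (kk in 1:3) u[, , , kk] <- array(0.2 * w[, kk], d)
  m <- deformationMetrics(DisplacementField(u))
  expect_within(max(abs(imgData(m$jacobian) - 1.728)), 0, 1e-6)
  expect_lt(max(imgData(m$adi)), 1e-6)
  # uniaxial stretch (2, 1, 1)
  u2 <- array(0, c(d, 3))
  u2[, , , 1] <- array(1 * w[, 1], d)
  m2 <- deformationMetrics(DisplacementField(u2))
  expect_within(max(abs(imgData(m2$jacobian) - 2)), 0, 1e-9)
  expect_within(max(abs(imgData(m2$adi) - 1)), 0, 1e-9)
})

test_that("Jacobians compose multiplicatively for small deformations", {
  set.seed(8)
  d <- c(20, 20, 20)
  mk <- function() {
    u <- array(0, c(d, 3))
    for (k in 1:3)
      u[, , , k] <- spectqct:::gaussBlur3d(array(rnorm(prod(d)), d), 3) * 3
    u
  }
  u1 <- mk(); u2 <- mk()
  expect_lt(max(abs(u1)), 1)   # well below one voxel
  gi <- spectqct:::gridIndices(d)
  comp <- array(0, c(d, 3))
  phi <- gi + matrix(u1, ncol = 3)
  for (k in 1:3)
    comp[, , , k] <- u1[, , , k] +
      array(spectqct:::interpArray(u2[, , , k], phi, fill = NULL), d)
  J1 <- imgData(deformationMetrics(DisplacementField(u1))$jacobian)
  J2 <- imgData(deformationMetrics(DisplacementField(u2))$jacobian)
  Jc <- imgData(deformationMetrics(DisplacementField(comp))$jacobian)
  core <- 4:17
  rel <- abs(Jc - J1 * J2)[core, core, core] / (J1 * J2)[core, core, core]
  expect_lt(max(rel), 0.05)
})

test_that("warping honors zero fields, constant shifts, and conservation", {
  d <- c(20, 20, 20)
  set.seed(2)
  img <- ImageVolume(array(rnorm(prod(d)), d))
  zero <- DisplacementField(array(0, c(d, 3)))
  expect_equal(imgData(applyDisplacement(img, zero)), imgData(img),
               tolerance = 1e-12)
  # a delta spike moves opposite to a constant pull-back shift
  spike <- array(0, d); spike[10, 10, 10] <- 1
  shifted <- array(0, c(d, 3)); shifted[, , , 1] <- 3
  out <- applyDisplacement(ImageVolume(spike),
                           DisplacementField(shifted))
  expect_equal(which(imgData(out) == 1), which(array(seq_len(prod(d)),
               d) == ((10 - 3) + 9 * 20 + 9 * 400)))
  # counts conserved for a smooth near-incompressible field
  blob <- spectqct:::gaussBlur3d(spike, 2.5)
  u <- array(0, c(d, 3))
  set.seed(3)
  for (k in 1:3)
    u[, , , k] <- spectqct:::gaussBlur3d(array(rnorm(prod(d)), d), 4) * 4
  warped <- applyDisplacement(ImageVolume(blob), DisplacementField(u))
  expect_within(sum(imgData(warped)) / sum(blob), 1, 0.02)
})

test_that("MI affine registration recovers identity and known shifts", {
  ph <- fixture("miPhantom", makeCtPair(phantomSpec(
    gridShape = c(48, 48, 48), nHotspots = 0L, noiseModel = "none",
    seed = 5)))
  msk <- ph$lobes
  lw <- spectqct:::indexToWorld(spectqct:::gridIndices(gridDim(msk)),
                                spacing(msk), origin(msk))
  lw <- lw[as.vector(msk@data > 0), , drop = FALSE]
  lw <- lw[seq(1, nrow(lw), length.out = 500), , drop = FALSE]
  resid <- function(a, target) {
    got <- sweep(lw %*% t(a@matrix), 2, as.vector(a@translation), "+")
    mean(sqrt(rowSums((got - target)^2)))
  }
  # identity: within 0.1 voxel
  a0 <- affineRegisterMI(ph$insp, ph$insp, msk)
  expect_lt(resid(a0, lw), 0.1 * mean(spacing(msk)))
  # 8 mm translation: within 1 voxel
  mv <- ImageVolume(imgData(ph$insp), spacing(ph$insp), origin = c(8, 0, 0))
  a1 <- affineRegisterMI(mv, ph$insp, msk)
  expect_lt(resid(a1, cbind(lw[, 1] + 8, lw[, 2], lw[, 3])),
            mean(spacing(msk)))
  # MI is invariant to intensity rescaling of the moving image
  mv10 <- ImageVolume(10 * imgData(mv), spacing(mv), origin(mv))
  a2 <- affineRegisterMI(mv10, ph$insp, msk)
  got1 <- sweep(lw %*% t(a1@matrix), 2, as.vector(a1@translation), "+")
  expect_lt(resid(a2, got1), 1e-6)
  # degenerate inputs are refused
  cst <- ImageVolume(array(1, c(48, 48, 48)), spacing(ph$insp))
  expect_error(affineRegisterMI(cst, ph$insp, msk), "degenerate histogram")
  empty <- LabelMap(array(0L, c(48, 48, 48)), spacing(ph$insp))
  expect_error(affineRegisterMI(ph$insp, ph$insp, empty), "empty")
})

test_that("deformable registration recovers phantom fields", {
  rep <- pipelineReport()
  expect_lt(rep$registration$meanEndpointError_mm, 2)
  expect_within(rep$registration$tissueConservationRatio, 1, 0.02)
})

test_that("registering a volume to itself returns a near-zero field", {
  ph <- smallPhantom()
  fld <- deformableRegisterSSTVD(ph$insp, ph$insp, ph$lobes,
                                 levels = c(2L, 1L), iters = c(20L, 10L))
  mag <- sqrt(fld@vectors[, , , 1]^2 + fld@vectors[, , , 2]^2 +
              fld@vectors[, , , 3]^2)
  expect_lt(mean(mag[ph$lobes@data > 0]), 0.5)
})

test_that("registration endpoint error shrinks with deformation size", {
  mee <- vapply(c(2, 6), function(mag) {
    spec <- phantomSpec(gridShape = c(48, 48, 48), nHotspots = 0L,
                        noiseModel = "none", deformationMagnitude = mag,
                        seed = 5)
    ph <- makeCtPair(spec)
    fld <- deformableRegisterSSTVD(ph$exp, ph$insp, ph$lobes)
    lung <- ph$lobes@data > 0
    du <- fld@vectors - ph$truth@displacement@vectors
    mean(sqrt(du[, , , 1][lung]^2 + du[, , , 2][lung]^2 +
              du[, , , 3][lung]^2))
  }, 0)
  expect_lt(mee[1], mee[2] + 0.1)   # monotone within noise
})
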