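# Synthetic thorax phantom: paired CT-like volumes at two breath-holds,
# a 5-lobe label map, the true deformation between them, and a SPECT-like
# tracer volume, all with recorded ground truth.
#
# Construction principles:
#  * HU model: voxel HU = -1000 * (1 - beta_tissue), air -1000, soft
#    tissue 0, so the tissue fraction is invertible from HU.
#  * The deflation field is a uniform contraction toward the thorax
#    centre plus a compact volume-source field at every diseased blob,
#    so gas-trapped and emphysematous lung fails to empty while healthy
#    lung compresses, with exactly controlled J and no folding.
#  * Tissue mass is preserved exactly: the deflated volume is rendered by
#    inverse-warping the inflated tissue-fraction map and scaling it by
#    1/J (J = local volume-change ratio of the true field).
#  * Tissue fractions are drawn per PRM class *conditionally on the local
#    J*, so that every lung voxel of the pair satisfies its seeded
#    parametric-response-map class under the standard -950/-856 HU
#    thresholds by construction; only interpolation can blur the classes.

.PRM_BETA_INSP <- 0.05    # beta at the -950 HU inspiration threshold
.PRM_BETA_EXP <- 0.144    # beta at the -856 HU expiration threshold
.BODY_HU <- 40            # uniform soft tissue outside the lung

#' Create a phantom specification
#'
#' Defaults describe the emulated study conditions: CT-like grids with a
#' SPECT companion at 3.9 mm resolution, disease burdens around the
#' cohort means (about 12\% fSAD and 13\% emphysema of lung voxels), a
#' couple of ventilation hot spots, a peak deflation displacement of
#' 6 mm (a breath-hold pair at the phantom's half scale), and Poisson
#' counting noise on the tracer image.
#'
#' @param gridShape integer(3) voxels per axis (>= 16).
#' @param ctSpacing numeric(3) CT voxel size in mm.
#' @param spectSpacing numeric(3) SPECT voxel size in mm.
#' @param fsadFraction target fraction of lung voxels seeded as
#'   functional small airway disease.
#' @param emphFraction target fraction seeded as emphysema.
#' @param nHotspots number of tracer hot spots.
#' @param hotspotAmplitude multiplicative tracer boost at a hot-spot
#'   centre (> 1).
#' @param deformationMagnitude peak displacement in mm between the
#'   inflated and deflated volumes.
#' @param noiseModel "none" or "poisson".
#' @param seed integer seed; the phantom is a deterministic function of
#'   the full specification.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(gridShape = c(32, 32, 32), seed = 1)
#' spec
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 64L),
                        ctSpacing = c(2, 2, 2),
                        spectSpacing = c(3.9, 3.9, 3.9),
                        fsadFraction = 0.12, emphFraction = 0.13,
                        nHotspots = 2L, hotspotAmplitude = 5,
                        deformationMagnitude = 6,
                        noiseModel = c("poisson", "none"),
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      ctSpacing = as.numeric(rep(ctSpacing, length.out = 3)),
      spectSpacing = as.numeric(rep(spectSpacing, length.out = 3)),
      fsadFraction = fsadFraction, emphFraction = emphFraction,
      nHotspots = as.integer(nHotspots),
      hotspotAmplitude = hotspotAmplitude,
      deformationMagnitude = deformationMagnitude,
      noiseModel = match.arg(noiseModel), seed = as.integer(seed))
}

# run expr under a local, seeded RNG without disturbing the caller's
withPhantomSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
         globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# two-ellipsoid, five-lobe lung geometry on the phantom grid
.lungGeometry <- function(dims, sp) {
  ext <- dims * sp
  idx <- gridIndices(dims)
  w <- indexToWorld(idx, sp, c(0, 0, 0))
  ctr <- ext / 2
  semi <- c(0.17, 0.27, 0.39) * ext
  mkLung <- function(side) {
    c0 <- ctr + c(side * 0.23 * ext[1], 0, 0)
    q <- ((w[, 1] - c0[1]) / semi[1])^2 + ((w[, 2] - c0[2]) / semi[2])^2 +
         ((w[, 3] - c0[3]) / semi[3])^2
    q <= 1
  }
  left <- mkLung(-1); right <- mkLung(1)
  lab <- integer(nrow(w))
  dz <- w[, 3] - ctr[3]; dy <- w[, 2] - ctr[2]
  # left lung: oblique fissure splits upper from lower
  lab[left] <- ifelse(dz[left] > 0.3 * dy[left], 1L, 2L)            # LUL/LLL
  # right lung: upper, middle (anterior mid-height) and lower lobes
  rul <- right & dz > 0.33 * semi[3]
  rml <- right & !rul & dz > -0.1 * semi[3] & dy < 0
  lab[rul] <- 3L; lab[rml] <- 4L
  lab[right & lab == 0L] <- 5L                                       # RLL
  list(label = array(lab, dims), world = w, center = ctr)
}

# greedy spherical seeding of `target` voxels among `free` lung voxels;
# returns the taken set plus the blob centres/radii (world mm)
.seedBlobs <- function(world, lungIdx, free, target, radiusRange = c(8, 14)) {
  taken <- logical(length(lungIdx))
  blobs <- NULL
  remaining <- target
  guard <- 0L
  while (remaining > 0L && any(free & !taken) && guard < 1000L) {
    guard <- guard + 1L
    cand <- which(free & !taken)
    ctr <- world[lungIdx[sample(cand, 1L)], ]
    r <- runif(1, radiusRange[1], radiusRange[2])
    d2 <- (world[lungIdx, 1] - ctr[1])^2 + (world[lungIdx, 2] - ctr[2])^2 +
          (world[lungIdx, 3] - ctr[3])^2
    hit <- which(free & !taken & d2 <= r^2)
    if (!length(hit)) next
    if (length(hit) > remaining) hit <- hit[order(d2[hit])][seq_len(remaining)]
    taken[hit] <- TRUE
    blobs <- rbind(blobs, c(ctr, r))
    remaining <- remaining - length(hit)
  }
  list(taken = taken, blobs = blobs)
}

# iterative inversion of y = x + u(x): returns fractional grid indices of
# x for every grid point y (clamped interpolation of u)
.inverseWarpIndices <- function(u, sp, iters = 12L) {
  d <- dim(u)[1:3]
  yIdx <- gridIndices(d)
  xIdx <- yIdx
  for (it in seq_len(iters)) {
    ux <- cbind(interpArray(u[, , , 1], xIdx, fill = NULL),
                interpArray(u[, , , 2], xIdx, fill = NULL),
                interpArray(u[, , , 3], xIdx, fill = NULL))
    xIdx <- yIdx - sweep(ux, 2, sp, "/")
  }
  xIdx
}

#' Generate a paired inflated/deflated CT phantom with ground truth
#'
#' Builds a five-lobe ellipsoidal lung, seeds gas-trapped (fSAD) and
#' emphysematous regions as spherical blobs to the requested voxel
#' fractions, constructs a smooth deflation field in which diseased
#' blobs retain air (reduced local compression, exactly controlled J),
#' and renders the deflated volume by mass-preserving inverse warping
#' (tissue fraction scales by 1/J).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements \code{insp} and \code{exp}
#'   ([ImageVolume-class] HU volumes on the same grid), \code{lobes}
#'   ([LabelMap-class] on the inflated grid) and \code{truth}
#'   ([PhantomTruth-class]).
#' @examples
#' ph <- makeCtPair(phantomSpec(gridShape = c(32, 32, 32), seed = 7))
#' ph$truth
#' @export
makeCtPair <- function(spec) {
  validObject(spec)
  dims <- spec@gridShape; sp <- spec@ctSpacing
  withPhantomSeed(spec@seed, {
    geo <- .lungGeometry(dims, sp)
    lab <- geo$label
    fullLung <- lab > 0L
    # the analysis mask sits a few voxels inside the pleura, as a real
    # lung segmentation does, keeping pleural partial-volume voxels out
    # of the label map while HU is generated over the full lung
    eroded <- erodeMask(fullLung, if (min(dims) >= 48L) 4L else 2L)
    lab[!eroded] <- 0L
    lungIdx <- which(lab > 0L)
    nLung <- length(lungIdx)
    stopifnot3(nLung > 0L, "degenerate grid: no lung voxels")
    rimIdx <- which(fullLung & !eroded)

    # --- seed disease classes -------------------------------------------
    nEmph <- round(spec@emphFraction * nLung)
    nFsad <- round(spec@fsadFraction * nLung)
    sE <- .seedBlobs(geo$world, lungIdx, rep(TRUE, nLung), nEmph)
    sF <- .seedBlobs(geo$world, lungIdx, !sE$taken, nFsad)
    isEmph <- sE$taken; isFsad <- sF$taken
    classVec <- rep(1L, nLung)          # 1 Normal, 2 fSAD, 3 Emph
    classVec[isFsad] <- 2L; classVec[isEmph] <- 3L
    classMapArr <- array(0L, dims); classMapArr[lungIdx] <- classVec

    # --- true deformation ------------------------------------------------
    # uniform contraction toward the thorax centre (healthy deflation,
    # J = (1 - s0)^3 exactly) plus a compact volume-source field at each
    # diseased blob: inside a blob the source gradient is isotropic, so
    # J = (1 - s0 + coef)^3 exactly -- gas-trapped and emphysematous lung
    # retains air (only 40% of the healthy regional air-volume change),
    # and J never folds. Outside a blob the source decays as 1/r^2
    # (divergence-free), leaving healthy-lung J untouched to first order.
    distC <- sqrt(rowSums(sweep(geo$world[lungIdx, , drop = FALSE], 2,
                                geo$center, "-")^2))
    s0 <- if (spec@deformationMagnitude > 0)
      spec@deformationMagnitude / max(distC) else 0
    u <- array(0, c(dims, 3))
    for (k in 1:3)
      u[, , , k] <- array(-s0 * (geo$world[, k] - geo$center[k]), dims)
    # gas-trapped blobs keep 55% of the healthy regional ventilation,
    # emphysematous blobs trap at half that strength
    blobs <- rbind(if (!is.null(sE$blobs)) cbind(sE$blobs, 0.5),
                   if (!is.null(sF$blobs)) cbind(sF$blobs, 1))
    if (s0 > 0 && !is.null(blobs)) {
      ventRetain <- 0.55
      Jn <- (1 - s0)^3
      Jdisease <- 1 - ventRetain * (1 - Jn)
      coef0 <- Jdisease^(1 / 3) - (1 - s0)
      uFlat <- matrix(u, ncol = 3L)
      w <- 2 * mean(sp)   # smooth inner-to-outer ramp, keeps J continuous
      for (b in seq_len(nrow(blobs))) {
        coef <- coef0 * blobs[b, 5]
        dx <- sweep(geo$world, 2, blobs[b, 1:3], "-")
        r <- sqrt(rowSums(dx^2))
        a <- blobs[b, 4]
        t <- pmin(pmax((r - (a - w)) / (2 * w), 0), 1)
        s <- t * t * (3 - 2 * t)
        fac <- coef * ((1 - s) + s * (a / pmax(r, 1e-6))^3)
        uFlat <- uFlat + dx * fac
      }
      u <- array(uFlat, c(dims, 3))
    }
    J <- .fieldJacobianArr(u, sp)

    # --- tissue fractions conditional on class and local J --------------
    tex <- gaussBlur3d(array(runif(prod(dims)), dims), 1.5)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))
    tL <- tex[lungIdx]; jL <- J[lungIdx]
    beta <- numeric(nLung)
    nrm <- classVec == 1L
    beta[nrm] <- pmax(jL[nrm] * (0.167 + 0.01 * tL[nrm]), 0.052)
    fs <- classVec == 2L
    beta[fs] <- pmax(jL[fs] * (0.12 + 0.013 * tL[fs]), 0.052)
    em <- classVec == 3L
    beta[em] <- 0.028 + 0.017 * tL[em]
    betaInsp <- array(1 + .BODY_HU / 1000, dims)   # body
    betaInsp[lungIdx] <- beta
    # pleural rim: normal-lung tissue outside the analysis mask
    betaInsp[rimIdx] <- pmax(J[rimIdx] * (0.167 + 0.01 * tex[rimIdx]),
                             0.052)

    inspHU <- -1000 * (1 - betaInsp)

    # --- render deflated volume by mass-preserving inverse warp ---------
    if (spec@deformationMagnitude > 0) {
      xIdx <- .inverseWarpIndices(u, sp)
      lungNum <- (fullLung) + 0
      inLungExp <- interpArray(lungNum, xIdx, fill = 0) > 0.5
      bI <- interpArray(betaInsp, xIdx, fill = NULL)
      jI <- pmax(interpArray(J, xIdx, fill = NULL), 1e-6)
      betaExp <- ifelse(inLungExp, pmin(bI / jI, 1), 1 + .BODY_HU / 1000)
      expHU <- array(-1000 * (1 - betaExp), dims)
    } else {
      expHU <- inspHU
    }

    # --- ground truth ----------------------------------------------------
    dvair <- (1 - J[lungIdx]) * prod(sp)
    lobeOf <- lab[lungIdx]
    lobNames <- c("LUL", "LLL", "RUL", "RML", "RLL")
    perLobe <- vapply(1:5, function(l) sum(dvair[lobeOf == l]), 0)
    lobar <- if (abs(sum(perLobe)) > 1e-9) perLobe / sum(perLobe)
             else tabulate(lobeOf, 5L) / nLung
    names(lobar) <- lobNames
    lobar <- lobar / sum(lobar)

    # hot spots sit at the centres of the first gas-trapped blobs (focal
    # deposition at the narrowed airways feeding trapped regions); their
    # positions are therefore stable when the seeded fraction grows,
    # because blob seeding is nested under a fixed seed
    centers <- matrix(integer(0), 0L, 3L)
    if (spec@nHotspots > 0L) {
      ctrs <- sF$blobs
      nb <- if (is.null(ctrs)) 0L else min(nrow(ctrs), spec@nHotspots)
      if (nb > 0L) {
        ijk <- round(worldToIndex(ctrs[seq_len(nb), 1:3, drop = FALSE],
                                  sp, c(0, 0, 0)))
        centers <- rbind(centers, ijk)
      }
      extra <- spec@nHotspots - nrow(centers)
      if (extra > 0L) {
        pick <- sample(lungIdx, extra, replace = length(lungIdx) < extra)
        centers <- rbind(centers, arrayInd(pick, dims))
      }
      storage.mode(centers) <- "integer"
    }

    lobes <- LabelMap(lab, spacing = sp,
                      labels = setNames(1:5, lobNames))
    truth <- new("PhantomTruth",
      classMap = LabelMap(classMapArr, spacing = sp,
                          labels = c(Normal = 1L, fSAD = 2L, Emph = 3L)),
      displacement = DisplacementField(u, spacing = sp),
      hotspotCenters = centers, lobarVentilation = lobar,
      spectOffset = AffineTransform())

    list(insp = ImageVolume(inspHU, spacing = sp),
         exp = ImageVolume(expHU, spacing = sp),
         lobes = lobes, truth = truth)
  })
}

#' Generate the SPECT-like tracer volume for a phantom
#'
#' Tracer concentration is proportional to the per-voxel air-volume
#' change (1 - J, clipped at zero), boosted by Gaussian multiplicative
#' hot-spot kernels (sigma = 2 SPECT voxels) centred in gas-trapped
#' regions, pushed to the deflated (tidal-like) domain, blurred to SPECT
#' resolution, resampled onto the coarse SPECT grid, misaligned by a
#' random rigid transform recorded in the returned truth, and optionally
#' degraded with Poisson counting noise.
#'
#' @param spec the [PhantomSpec-class] used for the CT pair.
#' @param truth the [PhantomTruth-class] from [makeCtPair()].
#' @param lobes the [LabelMap-class] from [makeCtPair()].
#' @param meanCounts target mean tracer count per lung voxel before noise.
#' @return list with \code{spect} (an [ImageVolume-class] on the SPECT
#'   grid) and \code{truth} (the input truth with \code{spectOffset}
#'   filled in).
#' @export
makeSpect <- function(spec, truth, lobes, meanCounts = 80) {
  validObject(spec)
  stopifnot3(length(truth@displacement@vectors) > 1,
             "phantom truth lacks a displacement field")
  stopifnot3(all(gridDim(truth@displacement) == gridDim(lobes)),
             "truth and lobes must share the CT grid")
  dims <- gridDim(lobes); sp <- spacing(lobes)
  withPhantomSeed(spec@seed + 1000L, {
    u <- truth@displacement@vectors
    J <- .fieldJacobianArr(u, sp)
    lung <- lobes@data > 0L
    vent <- pmax(1 - J, 0)
    vent[!lung] <- 0
    if (all(vent == 0)) vent[lung] <- 1   # identity deformation: uniform

    # hot-spot kernels, applied in the deflated-domain world frame
    sigHot <- 2 * mean(spec@spectSpacing)
    hotW <- NULL
    if (nrow(truth@hotspotCenters)) {
      cw <- indexToWorld(truth@hotspotCenters, sp, c(0, 0, 0))
      n <- nrow(cw)
      idx4 <- cbind(truth@hotspotCenters[rep(seq_len(n), 3L), , drop = FALSE],
                    rep(1:3, each = n))
      uc <- matrix(u[idx4], ncol = 3)
      hotW <- cw + uc
    }

    # push ventilation to the deflated domain (extending it outward
    # first, so interpolation near the mask edge does not blend zeros)
    if (max(abs(u)) > 0) {
      ventExt <- extendOutward(vent, lung, passes = 4L)
      xIdx <- .inverseWarpIndices(u, sp)
      lungNum <- (lung) + 0
      lungExp <- array(interpArray(lungNum, xIdx, fill = 0) > 0.5, dims)
      tracer <- array(interpArray(ventExt, xIdx, fill = 0), dims)
      tracer[!lungExp] <- 0
    } else {
      lungExp <- lung
      tracer <- vent
    }
    if (!is.null(hotW)) {
      w <- indexToWorld(gridIndices(dims), sp, c(0, 0, 0))
      mult <- rep(1, nrow(w))
      for (h in seq_len(nrow(hotW))) {
        d2 <- (w[, 1] - hotW[h, 1])^2 + (w[, 2] - hotW[h, 2])^2 +
              (w[, 3] - hotW[h, 3])^2
        mult <- mult * (1 + (spec@hotspotAmplitude - 1) *
                        exp(-d2 / (2 * sigHot^2)))
      }
      tracer <- tracer * array(mult, dims)
    }

    # nearest-tissue extension avoids a partial-volume rim at the small
    # phantom lung size, then blur to SPECT resolution (FWHM = spacing)
    sigBlur <- mean(spec@spectSpacing) / 2.355
    # reach ~2 SPECT voxels beyond the lung so neither the blur nor the
    # coarse-grid resampling drags the lung rim toward zero
    passes <- max(3L, ceiling((2 * mean(spec@spectSpacing) +
                               3 * sigBlur) / min(sp)))
    tracer <- extendOutward(tracer, lungExp, passes = passes)
    tracer <- gaussBlur3d(tracer, sigBlur / sp)

    # rigid misalignment: small in-plane rotation plus translation
    ctr <- dims * sp / 2
    theta <- runif(1, -3, 3) * pi / 180
    R <- diag(3)
    R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                            -sin(theta), cos(theta)), 2)
    tOff <- runif(3, -6, 6)
    off <- AffineTransform(R, ctr - R %*% ctr + tOff)
    offInv <- invertAffine(off)

    sdims <- pmax(as.integer(ceiling(dims * sp / spec@spectSpacing)), 4L)
    sw <- indexToWorld(gridIndices(sdims), spec@spectSpacing, c(0, 0, 0))
    src <- sweep(sw %*% t(offInv@matrix), 2, as.vector(offInv@translation),
                 "+")
    vals <- interpArray(tracer, worldToIndex(src, sp, c(0, 0, 0)), fill = 0)
    pos <- vals[vals > 0]
    if (length(pos)) vals <- vals / mean(pos) * meanCounts
    if (spec@noiseModel == "poisson") vals <- rpois(length(vals),
                                                    pmax(vals, 0))
    spect <- ImageVolume(array(as.numeric(vals), sdims),
                         spacing = spec@spectSpacing)
    truth@spectOffset <- off
    list(spect = spect, truth = truth)
  })
}

#' Simulate a two-wave bivariate panel with a known cross-lagged effect
#'
#' Generates an fSAD-like exposure x and a ventilation-heterogeneity-like
#' outcome y at two waves: x1 and y1 are standard normal with synchronous
#' correlation \code{sync}; x2 follows x1 with autocorrelation
#' \code{stabilityX}; y2 follows y1 with autocorrelation
#' \code{stabilityY} plus the causal cross-lagged path
#' \code{crossLagEffect} from x1. The reverse path (y1 to x2) is zero, so
#' the true partial cross-lagged correlation r(y1, x2 | x1) is exactly
#' zero and the x-to-y direction is the only real signal.
#'
#' @param nSubjects panel size (>= 8).
#' @param crossLagEffect coefficient of x1 in y2.
#' @param seed integer RNG seed.
#' @param stabilityX,stabilityY wave-1 to wave-2 autocorrelations.
#' @param sync synchronous correlation of x1 and y1.
#' @return data.frame with columns subject, x1, y1, x2, y2.
#' @examples
#' d <- makePanelDataset(50, crossLagEffect = 0.5, seed = 1)
#' head(d)
#' @export
makePanelDataset <- function(nSubjects, crossLagEffect, seed,
                             stabilityX = 0.6, stabilityY = 0.6,
                             sync = 0.5) {
  stopifnot3(nSubjects >= 8, "nSubjects must be >= 8")
  for (r in c(stabilityX, stabilityY, sync))
    stopifnot3(abs(r) <= 1, "correlations must lie in [-1, 1]")
  varY2res <- 1 - (stabilityY^2 + crossLagEffect^2 +
                   2 * stabilityY * crossLagEffect * sync)
  # implied covariance of (x1, y1, x2, y2) must be positive definite
  S <- matrix(0, 4, 4)
  S[1, ] <- c(1, sync, stabilityX, stabilityY * sync + crossLagEffect)
  S[2, ] <- c(sync, 1, stabilityX * sync, stabilityY + crossLagEffect * sync)
  S[3, ] <- c(S[1, 3], S[2, 3], 1, stabilityX * S[1, 4])
  S[4, ] <- c(S[1, 4], S[2, 4], S[3, 4], 1)
  if (varY2res <= 0 || inherits(try(chol(S), silent = TRUE), "try-error"))
    stop("implied covariance is not positive definite for these parameters",
         call. = FALSE)
  withPhantomSeed(as.integer(seed), {
    x1 <- rnorm(nSubjects)
    y1 <- sync * x1 + sqrt(1 - sync^2) * rnorm(nSubjects)
    x2 <- stabilityX * x1 + sqrt(1 - stabilityX^2) * rnorm(nSubjects)
    y2 <- stabilityY * y1 + crossLagEffect * x1 +
          sqrt(varY2res) * rnorm(nSubjects)
    data.frame(subject = seq_len(nSubjects), x1 = x1, y1 = y1,
               x2 = x2, y2 = y2)
  })
}

#' Write a phantom to disk as NIfTI volumes plus a truth sidecar
#'
#' @param phantom the list returned by [makeCtPair()], optionally with a
#'   \code{spect} element from [makeSpect()].
#' @param outdir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(phantom, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeVolume(phantom$insp, file.path(outdir, "ct_insp.nii.gz"))
  writeVolume(phantom$exp, file.path(outdir, "ct_exp.nii.gz"))
  writeVolume(phantom$lobes, file.path(outdir, "lobes.nii.gz"))
  writeVolume(phantom$truth@displacement,
              file.path(outdir, "true_displacement.nii.gz"))
  writeVolume(phantom$truth@classMap, file.path(outdir, "true_class.nii.gz"))
  if (!is.null(phantom$spect))
    writeVolume(phantom$spect, file.path(outdir, "spect.nii.gz"))
  off <- phantom$truth@spectOffset
  sidecar <- c(
    sprintf("lobar_ventilation,%s",
            paste(sprintf("%s=%.9f", names(phantom$truth@lobarVentilation),
                          phantom$truth@lobarVentilation), collapse = ";")),
    sprintf("spect_offset_translation,%s",
            paste(signif(off@translation, 9), collapse = ";")),
    sprintf("n_hotspots,%d", nrow(phantom$truth@hotspotCenters)))
  writeLines(sidecar, file.path(outdir, "truth.csv"))
  invisible(outdir)
}
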