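# Registration: mutual-information affine alignment of SPECT to CT,
# mass-preserving deformable registration of the deflated to the inflated
# CT, warping, and deformation metrics (Jacobian determinant, anisotropic
# deformation index).

## ---- deformation metrics ------------------------------------------------

# Jacobian determinant det(I + grad u) of a 4D displacement array (mm),
# gradients by central differences in world units.
.fieldJacobianArr <- function(u, sp) {
  g <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3)
    g[[(i - 1) * 3 + j]] <- diffAxis(u[, , , i], j) / sp[j] +
      (if (i == j) 1 else 0)
  F11 <- g[[1]]; F12 <- g[[2]]; F13 <- g[[3]]
  F21 <- g[[4]]; F22 <- g[[5]]; F23 <- g[[6]]
  F31 <- g[[7]]; F32 <- g[[8]]; F33 <- g[[9]]
  F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}

# eigenvalues of the symmetric right Cauchy-Green tensor C = F^T F per
# voxel, via the closed-form trigonometric solution; returns list of
# three arrays, descending.
.symEig3 <- function(C11, C22, C33, C12, C13, C23) {
  q <- (C11 + C22 + C33) / 3
  p2 <- (C11 - q)^2 + (C22 - q)^2 + (C33 - q)^2 +
        2 * (C12^2 + C13^2 + C23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  ok <- p > 1e-12
  B11 <- ifelse(ok, (C11 - q) / p, 0); B22 <- ifelse(ok, (C22 - q) / p, 0)
  B33 <- ifelse(ok, (C33 - q) / p, 0)
  B12 <- ifelse(ok, C12 / p, 0); B13 <- ifelse(ok, C13 / p, 0)
  B23 <- ifelse(ok, C23 / p, 0)
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
          B13 * (B12 * B23 - B22 * B13)
  phi <- acos(pmin(pmax(detB / 2, -1), 1)) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  list(e1, e2, e3)
}

#' Jacobian determinant and anisotropic deformation index of a field
#'
#' The Jacobian determinant J = det(I + grad u) is the local volume-
#' change ratio of the deformation (J > 1 expansion, J < 1 compression).
#' The anisotropic deformation index (ADI) measures how directionally
#' non-uniform the local deformation is, from the principal stretches
#' lambda1 >= lambda2 >= lambda3 of the right stretch tensor:
#' \deqn{ADI = \sqrt{((\lambda_1-\lambda_2)/\lambda_2)^2 +
#'   ((\lambda_2-\lambda_3)/\lambda_3)^2}}
#' ADI is zero wherever the deformation is locally isotropic.
#'
#' @param field a [DisplacementField-class].
#' @return list with \code{jacobian} and \code{adi}, both
#'   [ImageVolume-class] on the field grid.
#' @examples
#' u <- array(0, c(8, 8, 8, 3))
#' m <- deformationMetrics(DisplacementField(u))
#' range(imgData(m$jacobian))  # identically 1
#' @export
deformationMetrics <- function(field) {
  u <- field@vectors; sp <- field@spacing
  stopifnot3(all(is.finite(u)), "non-finite displacements")
  g <- vector("list", 9L)
  for (i in 1:3) for (j in 1:3)
    g[[(i - 1) * 3 + j]] <- diffAxis(u[, , , i], j) / sp[j] +
      (if (i == j) 1 else 0)
  F11 <- g[[1]]; F12 <- g[[2]]; F13 <- g[[3]]
  F21 <- g[[4]]; F22 <- g[[5]]; F23 <- g[[6]]
  F31 <- g[[7]]; F32 <- g[[8]]; F33 <- g[[9]]
  J <- F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
       F13 * (F21 * F32 - F22 * F31)
  C11 <- F11^2 + F21^2 + F31^2
  C22 <- F12^2 + F22^2 + F32^2
  C33 <- F13^2 + F23^2 + F33^2
  C12 <- F11 * F12 + F21 * F22 + F31 * F32
  C13 <- F11 * F13 + F21 * F23 + F31 * F33
  C23 <- F12 * F13 + F22 * F23 + F32 * F33
  ev <- .symEig3(C11, C22, C33, C12, C13, C23)
  l1 <- sqrt(pmax(ev[[1]], 0)); l2 <- sqrt(pmax(ev[[2]], 1e-300))
  l3 <- sqrt(pmax(ev[[3]], 1e-300))
  adi <- sqrt(((l1 - l2) / l2)^2 + ((l2 - l3) / l3)^2)
  list(jacobian = ImageVolume(array(J, dim(u)[1:3]), sp, field@origin),
       adi = ImageVolume(array(adi, dim(u)[1:3]), sp, field@origin))
}

## ---- warping ------------------------------------------------------------

#' Warp an image through a displacement field
#'
#' Resamples \code{img} onto the fixed grid of \code{field} in pull-back
#' convention: the output at fixed point x is \code{img} sampled at
#' x + u(x).
#'
#' @param img [ImageVolume-class] to warp (the moving image).
#' @param field [DisplacementField-class] on the fixed grid.
#' @param interpolation "linear" or "nearest" (use nearest for label
#'   maps).
#' @param fill value for out-of-domain samples.
#' @return an [ImageVolume-class] on the fixed grid.
#' @export
applyDisplacement <- function(img, field,
                              interpolation = c("linear", "nearest"),
                              fill = 0) {
  interpolation <- match.arg(interpolation)
  d <- dim(field@vectors)[1:3]
  xw <- indexToWorld(gridIndices(d), field@spacing, field@origin)
  tw <- xw + matrix(field@vectors, ncol = 3L)
  idx <- worldToIndex(tw, img@spacing, img@origin)
  vals <- interpArray(img@data, idx, fill = fill, method = interpolation)
  ImageVolume(array(vals, d), field@spacing, field@origin)
}

#' Resample an image onto a reference grid through an affine transform
#'
#' The output at reference world point x is \code{img} sampled at
#' \code{A x + t} (pull-back), so passing the transform returned by
#' [affineRegisterMI()] resamples the moving image into the fixed frame.
#'
#' @param img moving [ImageVolume-class].
#' @param reference [ImageVolume-class] or [LabelMap-class] defining the
#'   output grid.
#' @param transform [AffineTransform-class]; identity when NULL.
#' @param interpolation "linear" or "nearest".
#' @param fill out-of-domain fill value.
#' @return an [ImageVolume-class] on the reference grid.
#' @export
resampleToGrid <- function(img, reference, transform = NULL,
                           interpolation = c("linear", "nearest"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  d <- gridDim(reference)
  xw <- indexToWorld(gridIndices(d), spacing(reference), origin(reference))
  if (!is.null(transform))
    xw <- sweep(xw %*% t(transform@matrix), 2,
                as.vector(transform@translation), "+")
  idx <- worldToIndex(xw, img@spacing, img@origin)
  vals <- interpArray(img@data, idx, fill = fill, method = interpolation)
  ImageVolume(array(vals, d), spacing(reference), origin(reference))
}

## ---- mutual-information affine registration -----------------------------

.miOf <- function(fv, mv, bins) {
  ok <- is.finite(mv)
  if (sum(ok) < 32L) return(NA_real_)
  fv <- fv[ok]; mv <- mv[ok]
  rf <- range(fv); rm_ <- range(mv)
  if (rf[2] <= rf[1] || rm_[2] <= rm_[1]) return(NA_real_)
  bi <- pmin(floor((fv - rf[1]) / (rf[2] - rf[1]) * bins) + 1L, bins)
  bj <- pmin(floor((mv - rm_[1]) / (rm_[2] - rm_[1]) * bins) + 1L, bins)
  jc <- tabulate((bi - 1L) * bins + bj, bins * bins)
  p <- jc / sum(jc)
  pm <- matrix(p, bins, bins)          # rows: moving bins, cols: fixed
  px <- colSums(pm); py <- rowSums(pm)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (rep(px, each = bins)[nz] * rep(py, bins)[nz])))
}

.affineFromParams <- function(theta, center, mode) {
  rx <- theta[4]; ry <- theta[5]; rz <- theta[6]
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3)
  A <- Rz %*% Ry %*% Rx
  if (mode == "affine") {
    A <- A %*% diag(exp(theta[7:9]))
    Sh <- diag(3); Sh[1, 2] <- theta[10]; Sh[1, 3] <- theta[11]
    Sh[2, 3] <- theta[12]
    A <- A %*% Sh
  }
  AffineTransform(A, center - A %*% center + theta[1:3])
}

#' Affine registration by mutual-information maximization
#'
#' Aligns a moving image (typically the SPECT tracer volume) to a fixed
#' image (typically the tidal-volume CT) by maximizing the mutual
#' information of their joint intensity histogram over rigid or full
#' affine parameters, multi-resolution coarse-to-fine with an initial
#' translation grid search for capture range. The joint histogram is
#' evaluated over the fixed-image mask dilated by about two voxels.
#'
#' @param moving [ImageVolume-class] to align.
#' @param fixed [ImageVolume-class] reference.
#' @param mask [LabelMap-class] or [ImageVolume-class] on the fixed grid;
#'   voxels > 0 enter the histogram.
#' @param mode "rigid" (translation + rotation) or "affine" (adds scales
#'   and shears).
#' @param bins histogram bins per axis.
#' @param levels downsampling strides, coarse to fine.
#' @param maxit Nelder-Mead iterations per level.
#' @param searchRange,searchStep translation grid search extent and step
#'   in mm at the coarsest level.
#' @param maxSamples cap on mask voxels entering the histogram.
#' @return an [AffineTransform-class] mapping fixed world points into the
#'   moving domain (pull-back), with attributes \code{mi} (final mutual
#'   information) and \code{converged}.
#' @export
affineRegisterMI <- function(moving, fixed, mask,
                             mode = c("rigid", "affine"), bins = 48L,
                             levels = c(2L, 1L), maxit = 800L,
                             searchRange = 10, searchStep = 5,
                             maxSamples = 20000L) {
  mode <- match.arg(mode)
  stopifnot3(any(mask@data > 0), "empty registration mask")
  mvals <- moving@data[is.finite(moving@data)]
  stopifnot3(diff(range(mvals)) > 0,
             "degenerate histogram: moving image has zero variance")
  stopifnot3(diff(range(fixed@data)) > 0,
             "degenerate histogram: fixed image has zero variance")

  nPar <- if (mode == "rigid") 6L else 12L
  theta <- numeric(nPar)
  pscale <- c(rep(1, 3), rep(0.02, 3),
              if (mode == "affine") c(rep(0.05, 3), rep(0.05, 3)))
  dil <- gaussBlur3d((mask@data > 0) + 0, 1) > 0.02   # ~2 voxel dilation

  for (li in seq_along(levels)) {
    s <- levels[li]
    fx <- downsampleArray(fixed@data, fixed@spacing, s)
    mk <- if (s > 1L) downsampleArray(dil + 0, fixed@spacing, s)$data > 0.5
          else dil
    mskIdx <- which(mk)
    if (length(mskIdx) > maxSamples)
      mskIdx <- mskIdx[seq(1L, length(mskIdx),
                           length.out = maxSamples)]
    ijk <- arrayInd(mskIdx, dim(fx$data))
    xw <- indexToWorld(ijk, fx$spacing, fixed@origin)
    fv <- fx$data[mskIdx]
    mv3 <- if (s > 1L) downsampleArray(moving@data, moving@spacing, s)
           else list(data = moving@data, spacing = moving@spacing)
    ctr <- colMeans(xw)
    negMI <- function(th) {
      tr <- .affineFromParams(th, ctr, mode)
      pw <- sweep(xw %*% t(tr@matrix), 2, as.vector(tr@translation), "+")
      mvv <- interpArray(mv3$data, worldToIndex(pw, mv3$spacing,
                                                moving@origin),
                         fill = NA_real_)
      mi <- .miOf(fv, mvv, bins)
      if (is.na(mi)) 10 else -mi
    }
    if (li == 1L && searchRange > 0) {
      gr <- seq(-searchRange, searchRange, by = searchStep)
      best <- negMI(theta)
      for (tx in gr) for (ty in gr) for (tz in gr) {
        th <- theta; th[1:3] <- theta[1:3] + c(tx, ty, tz)
        v <- negMI(th)
        if (v < best) { best <- v; bestTh <- th }
      }
      if (exists("bestTh", inherits = FALSE)) theta <- bestTh
    }
    opt <- stats::optim(theta, negMI, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9,
                                       parscale = pscale))
    theta <- opt$par
  }
  out <- .affineFromParams(theta, ctr, mode)
  attr(out, "mi") <- -opt$value
  attr(out, "converged") <- opt$convergence == 0L
  if (opt$convergence != 0L)
    warning("MI optimizer did not fully converge; final MI = ",
            signif(-opt$value, 4))
  out
}

## ---- mass-preserving deformable registration ----------------------------

#' Deformable registration minimizing tissue-volume mismatch
#'
#' Estimates the displacement field from the inflated (fixed) CT into the
#' deflated (moving) CT by iteratively reducing the squared difference of
#' local tissue volume, \eqn{\beta_{fixed}(x) - J(x)\,\beta_{moving}(x +
#' u(x))}, where beta is the HU-derived tissue fraction and J the local
#' volume-change ratio of the current field; the J factor makes the match
#' mass-preserving rather than intensity-preserving. The field is kept
#' smooth by Gaussian regularization of both the per-iteration update and
#' the accumulated field, in a coarse-to-fine multi-resolution scheme.
#'
#' @param exp deflated-lung [ImageVolume-class] (moving, HU).
#' @param insp inflated-lung [ImageVolume-class] (fixed, HU).
#' @param mask [LabelMap-class] lung mask on the fixed grid (used for the
#'   convergence measure; forces act everywhere).
#' @param levels downsampling strides, coarse to fine.
#' @param iters iterations per level.
#' @param sigmaFluid Gaussian sigma (voxels) smoothing each update.
#' @param sigmaDiffusion Gaussian sigma (voxels) smoothing the field.
#' @param tol early-stop threshold on the mean update magnitude, in
#'   voxels.
#' @return a [DisplacementField-class] on the fixed grid (pull-back:
#'   warping \code{exp} with it reproduces \code{insp}-frame anatomy),
#'   with attribute \code{iterations}.
#' @export
deformableRegisterSSTVD <- function(exp, insp, mask,
                                    levels = c(4L, 2L, 1L),
                                    iters = c(80L, 60L, 40L),
                                    sigmaFluid = 1, sigmaDiffusion = 0.75,
                                    tol = 0.02) {
  stopifnot3(all(gridDim(exp) == gridDim(insp)) &&
             all(abs(spacing(exp) - spacing(insp)) < 1e-9),
             "volumes must share a grid; resample first")
  stopifnot3(levels[length(levels)] == 1L,
             "the final level must be full resolution (stride 1)")
  bf0 <- pmin(pmax((insp@data + 1000) / 1000, 0), 1)
  bm0 <- pmin(pmax((exp@data + 1000) / 1000, 0), 1)
  sp0 <- insp@spacing
  dims0 <- gridDim(insp)
  mask0 <- (mask@data > 0) + 0
  u <- NULL
  iterTotal <- 0L
  iters <- rep(iters, length.out = length(levels))

  for (li in seq_along(levels)) {
    s <- levels[li]
    bf <- downsampleArray(bf0, sp0, s)
    bm <- downsampleArray(bm0, sp0, s)
    mk <- if (s > 1L) downsampleArray(mask0, sp0, s)$data > 0.25 else
      mask0 > 0
    sp <- bf$spacing
    d <- dim(bf$data)
    gi <- gridIndices(d)
    if (is.null(u)) {
      u <- array(0, c(d, 3))
    } else {
      # upsample previous-level field (mm values carry over directly)
      uNew <- array(0, c(d, 3))
      oldDims <- dim(u)[1:3]
      map <- sweep(sweep(gi - 1, 2, sp, "*"), 2, spOld, "/") + 1
      for (k in 1:3)
        uNew[, , , k] <- array(interpArray(u[, , , k], map, fill = NULL), d)
      u <- uNew
    }
    kappa <- mean(sp)
    for (it in seq_len(iters[li])) {
      iterTotal <- iterTotal + 1L
      phi <- gi + sweep(matrix(u, ncol = 3L), 2, sp, "/")
      w <- array(interpArray(bm$data, phi, fill = NULL), d)
      J <- .fieldJacobianArr(u, sp)
      mw <- pmax(J, 0.05) * w
      r <- bf$data - mw
      g1 <- diffAxis(mw, 1) / sp[1]
      g2 <- diffAxis(mw, 2) / sp[2]
      g3 <- diffAxis(mw, 3) / sp[3]
      den <- g1^2 + g2^2 + g3^2 + (r / kappa)^2
      scl <- ifelse(den > 1e-12, r / den, 0)
      step <- numeric(0)
      for (k in 1:3) {
        dk <- gaussBlur3d(scl * switch(k, g1, g2, g3), sigmaFluid)
        u[, , , k] <- u[, , , k] + dk
        step <- c(step, mean(abs(dk[mk])))
      }
      for (k in 1:3)
        u[, , , k] <- gaussBlur3d(u[, , , k], sigmaDiffusion)
      if (sum(step) / mean(sp) < tol) break
    }
    spOld <- sp
  }
  out <- DisplacementField(u, spacing = sp0, origin = insp@origin)
  attr(out, "iterations") <- iterTotal
  out
}
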