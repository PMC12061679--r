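# Low-level grid numerics shared by the phantom, registration and metric
# modules. Everything works in 1-based voxel indices internally; world
# coordinates (mm) are origin + (index - 1) * spacing.

#' Construct an ImageVolume
#'
#' @param data numeric 3D array.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) world position of voxel (1,1,1) in mm.
#' @return an [ImageVolume-class].
#' @examples
#' vol <- ImageVolume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(2, 2, 2))
#' spacing(vol)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @param data integer-valued 3D array (0 = background).
#' @param spacing,origin grid geometry, as for [ImageVolume()].
#' @param labels named integer vector of region labels.
#' @return a [LabelMap-class].
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     labels = integer(0)) {
  storage.mode(data) <- "integer"
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), labels = lab)
}

#' Construct a DisplacementField
#'
#' @param vectors 4D array (nx, ny, nz, 3) of mm displacements on the
#'   fixed grid (pull-back convention: fixed point x maps to x + u(x)).
#' @param spacing,origin fixed-grid geometry in mm.
#' @return a [DisplacementField-class].
#' @export
DisplacementField <- function(vectors, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct an AffineTransform
#'
#' @param matrix 3x3 matrix.
#' @param translation numeric(3) in mm.
#' @return an [AffineTransform-class].
#' @export
AffineTransform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  new("AffineTransform", matrix = matrix,
      translation = as.numeric(translation))
}

#' @rdname AffineTransform
#' @param x an AffineTransform.
#' @export
invertAffine <- function(x) {
  Ai <- solve(x@matrix)
  AffineTransform(Ai, -Ai %*% x@translation)
}

## world <-> index helpers -------------------------------------------------

worldToIndex <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
}

indexToWorld <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# n x 3 matrix of all voxel indices of a grid (column-major order)
gridIndices <- function(dims) {
  cbind(rep.int(seq_len(dims[1]), dims[2] * dims[3]),
        rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3]),
        rep(seq_len(dims[3]), each = dims[1] * dims[2]))
}

## interpolation -----------------------------------------------------------

# Trilinear (or nearest) interpolation of a 3D array at fractional 1-based
# indices. idx: n x 3. Out-of-domain points get `fill`, or are clamped to
# the boundary when fill is NULL.
interpArray <- function(a, idx, fill = 0, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(a)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
            idx[, 2] >= 1 & idx[, 2] <= d[2] &
            idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (is.null(fill)) {  # clamp
    idx[, 1] <- pmin(pmax(idx[, 1], 1), d[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1), d[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1), d[3])
  }
  if (method == "nearest") {
    i <- pmin(pmax(round(idx[, 1]), 1), d[1])
    j <- pmin(pmax(round(idx[, 2]), 1), d[2])
    k <- pmin(pmax(round(idx[, 3]), 1), d[3])
    out <- a[cbind(i, j, k)]
  } else {
    i0 <- pmin(pmax(floor(idx[, 1]), 1), d[1] - 1)
    j0 <- pmin(pmax(floor(idx[, 2]), 1), d[2] - 1)
    k0 <- pmin(pmax(floor(idx[, 3]), 1), d[3] - 1)
    fx <- pmin(pmax(idx[, 1] - i0, 0), 1)
    fy <- pmin(pmax(idx[, 2] - j0, 0), 1)
    fz <- pmin(pmax(idx[, 3] - k0, 0), 1)
    n1 <- d[1]; n12 <- d[1] * d[2]
    base <- i0 + (j0 - 1) * n1 + (k0 - 1) * n12
    out <- (1 - fz) * ((1 - fy) * ((1 - fx) * a[base] + fx * a[base + 1]) +
                       fy * ((1 - fx) * a[base + n1] + fx * a[base + n1 + 1])) +
           fz * ((1 - fy) * ((1 - fx) * a[base + n12] + fx * a[base + n12 + 1]) +
                 fy * ((1 - fx) * a[base + n12 + n1] +
                       fx * a[base + n12 + n1 + 1]))
  }
  if (!is.null(fill)) out[!inside] <- fill
  out
}

## separable Gaussian smoothing -------------------------------------------

gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# convolve along the first dimension of a 3D array, edges replicated
convAxis1 <- function(a, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(a)
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(d[1], r), , drop = FALSE])
  out <- matrix(0, d[1], ncol(m))
  for (t in seq_along(k))
    out <- out + k[t] * pad[t:(t + d[1] - 1L), , drop = FALSE]
  array(out, d)
}

# Gaussian blur of a 3D array; sigma in voxels, per axis (recycled)
gaussBlur3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  if (sigma[1] > 0) a <- convAxis1(a, gaussKernel1d(sigma[1]))
  if (sigma[2] > 0) a <- aperm(convAxis1(aperm(a, c(2, 1, 3)),
                                         gaussKernel1d(sigma[2])), c(2, 1, 3))
  if (sigma[3] > 0) a <- aperm(convAxis1(aperm(a, c(3, 2, 1)),
                                         gaussKernel1d(sigma[3])), c(3, 2, 1))
  a
}

## finite differences ------------------------------------------------------

# central-difference gradient along `axis` (one-sided at edges), per unit
# index; divide by spacing for mm^-1.
diffAxis <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, n, prod(d[-axis]))
  g <- m
  if (n >= 3L)
    g[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] -
                        m[1:(n - 2L), , drop = FALSE]) / 2
  g[1L, ] <- m[2L, ] - m[1L, ]
  g[n, ] <- m[n, ] - m[n - 1L, ]
  aperm(array(g, d[perm]), order(perm))
}

## grey-value nearest-tissue extension ------------------------------------

# Fill `a` outside `mask` by iteratively propagating the masked values
# outward (mean over already-filled 6-neighbours), `passes` voxels deep.
extendOutward <- function(a, mask, passes = 6L) {
  a[!mask] <- 0
  have <- mask
  shift1 <- function(x, axis, by) {
    d <- dim(x); idx <- lapply(d, seq_len)
    src <- idx; n <- d[axis]
    if (by == 1L) { idx[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1L) }
    else          { idx[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
    out <- array(0, d)
    out[idx[[1]], idx[[2]], idx[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (p in seq_len(passes)) {
    acc <- array(0, dim(a)); cnt <- array(0, dim(a))
    for (axis in 1:3) for (by in c(1L, -1L)) {
      acc <- acc + shift1(a * have, axis, by)
      cnt <- cnt + shift1(have + 0, axis, by)
    }
    newly <- !have & cnt > 0
    a[newly] <- acc[newly] / cnt[newly]
    have <- have | newly
  }
  a
}

## binary erosion ----------------------------------------------------------

# erode a logical 3D mask by `passes` voxels (6-connected)
erodeMask <- function(mask, passes = 1L) {
  d <- dim(mask)
  for (p in seq_len(passes)) {
    keep <- mask
    for (axis in 1:3) {
      idx <- lapply(d, seq_len); lo <- idx; hi <- idx
      n <- d[axis]
      lo[[axis]] <- c(1L, seq_len(n - 1L))   # replicate edge
      hi[[axis]] <- c(seq_len(n - 1L) + 1L, n)
      keep <- keep & mask[lo[[1]], lo[[2]], lo[[3]]] &
                     mask[hi[[1]], hi[[2]], hi[[3]]]
    }
    mask <- keep
  }
  mask
}

## downsampling ------------------------------------------------------------

# blur + stride subsample of an ImageVolume-like array; returns list with
# the array and its new spacing (origin unchanged: sample 1 kept).
downsampleArray <- function(a, spacing, stride) {
  if (stride <= 1L) return(list(data = a, spacing = spacing))
  sm <- gaussBlur3d(a, rep(stride / 2, 3))
  d <- dim(a)
  ix <- seq(1L, d[1], by = stride); iy <- seq(1L, d[2], by = stride)
  iz <- seq(1L, d[3], by = stride)
  list(data = sm[ix, iy, iz, drop = FALSE], spacing = spacing * stride)
}

stopifnot3 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
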