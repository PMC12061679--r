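#' @import methods
NULL

#' ImageVolume: a 3D scalar grid with physical geometry
#'
#' Container for a volumetric scalar image (CT Hounsfield units, tracer
#' counts, tissue fractions, ...) on a regular grid. World coordinates in
#' millimetres follow \code{world = origin + (index - 1) * spacing}, with
#' 1-based voxel indices.
#'
#' @slot data numeric 3D array of voxel values.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), world position (mm) of voxel (1,1,1).
#'
#' @seealso [ImageVolume()] for the constructor, [LabelMap-class],
#'   [DisplacementField-class]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "'data' must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite values (mm)")
  if (is.null(msg)) TRUE else msg
})

#' LabelMap: integer lobe labels on an image grid
#'
#' An [ImageVolume-class] whose voxel values are non-negative integer
#' region labels; 0 denotes background (not lung). The \code{labels} slot
#' names the positive labels (e.g. \code{c(LUL = 1, LLL = 2, ...)}).
#'
#' @slot labels named integer vector mapping region names to label values.
#' @export
setClass("LabelMap", contains = "ImageVolume",
  representation(labels = "integer"),
  prototype(labels = integer(0)))

setValidity("LabelMap", function(object) {
  msg <- NULL
  v <- object@data
  if (any(v[is.finite(v)] < 0) || any(v[is.finite(v)] != round(v[is.finite(v)])))
    msg <- c(msg, "label values must be non-negative integers")
  if (length(object@labels) &&
      (is.null(names(object@labels)) || any(!nzchar(names(object@labels)))))
    msg <- c(msg, "'labels' must be a named integer vector")
  if (is.null(msg)) TRUE else msg
})

#' DisplacementField: per-voxel 3-vectors on a fixed grid
#'
#' Displacements are stored in mm on the fixed grid, in pull-back
#' convention: a field \eqn{u} maps fixed-domain points \eqn{x} to
#' moving-domain points \eqn{x + u(x)}, so warping a moving image onto the
#' fixed grid samples it at \eqn{x + u(x)}.
#'
#' @slot vectors numeric 4D array \code{dim x dim y dim z x 3} of mm
#'   displacements.
#' @slot spacing numeric(3) fixed-grid spacing in mm.
#' @slot origin numeric(3) fixed-grid origin in mm.
#' @export
setClass("DisplacementField",
  representation(vectors = "array", spacing = "numeric", origin = "numeric"),
  prototype(vectors = array(0, c(1, 1, 1, 3)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("DisplacementField", function(object) {
  msg <- NULL
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "'vectors' must be a 4D array with last dimension 3")
  if (any(!is.finite(object@vectors)))
    msg <- c(msg, "displacements must be finite everywhere")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values (mm)")
  if (is.null(msg)) TRUE else msg
})

#' AffineTransform: a 3x3 matrix plus translation in mm
#'
#' Maps world points \eqn{x} (mm) to \eqn{A x + t}. Used both for the
#' recovered SPECT-to-CT alignment and for synthetic misalignments.
#'
#' @slot matrix 3x3 real matrix (invertible).
#' @slot translation numeric(3) in mm.
#' @export
setClass("AffineTransform",
  representation(matrix = "matrix", translation = "numeric"),
  prototype(matrix = diag(3), translation = c(0, 0, 0)))

setValidity("AffineTransform", function(object) {
  msg <- NULL
  if (!all(dim(object@matrix) == c(3L, 3L)))
    msg <- c(msg, "'matrix' must be 3x3")
  else if (abs(det(object@matrix)) <= 1e-9)
    msg <- c(msg, "'matrix' must be invertible (|det| > 1e-9)")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "'translation' must be 3 finite values (mm)")
  if (is.null(msg)) TRUE else msg
})

#' PhantomSpec: parameters of the synthetic thorax phantom
#'
#' Defines the simulated acquisition and disease burden for one phantom
#' subject: grid geometry for the CT-like and SPECT-like volumes, target
#' fractions of lung voxels seeded as functional small airway disease
#' (fSAD, gas trapping) and emphysema, ventilation hot spots, the peak
#' breath-hold-to-breath-hold displacement, and the counting-noise model.
#'
#' @slot gridShape integer(3) voxels per axis (>= 16 each).
#' @slot ctSpacing numeric(3) CT voxel size in mm.
#' @slot spectSpacing numeric(3) SPECT voxel size in mm.
#' @slot fsadFraction target fraction of lung voxels seeded as fSAD.
#' @slot emphFraction target fraction seeded as emphysema.
#' @slot nHotspots number of tracer hot spots (>= 0).
#' @slot hotspotAmplitude multiplicative tracer boost at a hot-spot
#'   centre (> 1).
#' @slot deformationMagnitude peak displacement between the paired lung
#'   volumes, in mm.
#' @slot noiseModel "none" or "poisson" (SPECT counting noise).
#' @slot seed integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", ctSpacing = "numeric",
    spectSpacing = "numeric", fsadFraction = "numeric",
    emphFraction = "numeric", nHotspots = "integer",
    hotspotAmplitude = "numeric", deformationMagnitude = "numeric",
    noiseModel = "character", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    msg <- c(msg, "grid must have >= 16 voxels per axis")
  if (any(object@ctSpacing <= 0) || any(object@spectSpacing <= 0))
    msg <- c(msg, "all spacings must be > 0")
  f <- c(object@fsadFraction, object@emphFraction)
  if (any(f < 0) || any(f > 1) || sum(f) > 1)
    msg <- c(msg, "fsadFraction + emphFraction must lie in [0, 1]")
  if (object@nHotspots < 0L)
    msg <- c(msg, "nHotspots must be >= 0")
  if (object@nHotspots > 0L && object@hotspotAmplitude <= 1)
    msg <- c(msg, "hotspotAmplitude must be > 1")
  if (object@deformationMagnitude < 0)
    msg <- c(msg, "deformationMagnitude must be >= 0 mm")
  if (!object@noiseModel %in% c("none", "poisson"))
    msg <- c(msg, "noiseModel must be 'none' or 'poisson'")
  if (is.null(msg)) TRUE else msg
})

#' PhantomTruth: generator ground truth for recovery tests
#'
#' @slot classMap [LabelMap-class] of per-voxel tissue classes inside the
#'   lung (1 = Normal, 2 = fSAD, 3 = Emph; 0 outside the lung).
#' @slot displacement true [DisplacementField-class] from the inflated
#'   (TLC) grid into the deflated (expiration) domain.
#' @slot hotspotCenters integer matrix (n x 3) of hot-spot centre voxel
#'   indices on the CT grid (0 rows when no hot spots were seeded).
#' @slot lobarVentilation named numeric of per-lobe air-volume-change
#'   fractions (sums to 1).
#' @slot spectOffset [AffineTransform-class] rigid misalignment applied to
#'   the SPECT volume (identity until [makeSpect()] fills it in).
#' @export
setClass("PhantomTruth",
  representation(classMap = "LabelMap", displacement = "DisplacementField",
    hotspotCenters = "matrix", lobarVentilation = "numeric",
    spectOffset = "AffineTransform"))

setValidity("PhantomTruth", function(object) {
  msg <- NULL
  lv <- object@lobarVentilation
  if (length(lv) && abs(sum(lv) - 1) > 1e-9)
    msg <- c(msg, "lobar ventilation fractions must sum to 1 (+/- 1e-9)")
  if (is.null(msg)) TRUE else msg
})

#' CorrelationResult: a Pearson correlation with effect-size category
#'
#' @slot r Pearson product-moment coefficient.
#' @slot n number of complete pairs used.
#' @slot p two-sided p-value from the t distribution with n - 2 df.
#' @slot strength effect-size band of |r|: negligible (<= 0.3),
#'   weak (0.3, 0.5], moderate (0.5, 0.7], strong (0.7, 0.9],
#'   very strong (> 0.9).
#' @export
setClass("CorrelationResult",
  representation(r = "numeric", n = "integer", p = "numeric",
                 strength = "character"))

#' CorrelationMap: a grid of correlations between two variable sets
#'
#' @slot r matrix of Pearson coefficients (SPECT variables x qCT
#'   variables).
#' @slot n matrix of pair counts.
#' @slot p matrix of two-sided p-values.
#' @slot strength character matrix of effect-size bands.
#' @slot highlighted logical matrix, TRUE where |r| > 0.7.
#' @slot mode which rows entered: pooled cross-sectional visits or
#'   between-visit deltas.
#' @export
setClass("CorrelationMap",
  representation(r = "matrix", n = "matrix", p = "matrix",
    strength = "matrix", highlighted = "matrix", mode = "character"))

#' EFAResult: principal-component factor solution with Varimax rotation
#'
#' @slot nFactors retained factor count.
#' @slot loadings variables x factors loading matrix after rotation.
#' @slot rotation the orthogonal rotation matrix applied.
#' @slot varianceExplainedPct percent of total variance retained.
#' @slot keyVariables per-factor list of variables with |loading| above
#'   the threshold.
#' @slot loadingThreshold the threshold used (default 0.6).
#' @export
setClass("EFAResult",
  representation(nFactors = "integer", loadings = "matrix",
    rotation = "matrix", varianceExplainedPct = "numeric",
    keyVariables = "list", loadingThreshold = "numeric"))

#' CrossLaggedResult: two-wave, two-variable cross-lagged panel analysis
#'
#' Six correlations in the classic panel layout: two synchronous
#' (r(x1,y1), r(x2,y2)), two stability (r(x1,x2), r(y1,y2)), and two
#' cross-lagged partial correlations with the same-variable stability
#' partialled out (r(x1,y2 | y1) and r(y1,x2 | x1)). Significance is
#' one-sided (greater than zero) against a t reference with n - 2 df for
#' simple and n - 3 df for partial correlations.
#'
#' @slot r named numeric(6): sync1, sync2, stab_x, stab_y, cross_xy,
#'   cross_yx.
#' @slot p named numeric(6) one-sided p-values.
#' @slot significant named logical(6) verdicts at \code{alpha}.
#' @slot alpha type-I error rate used for the verdicts.
#' @slot n complete cases used.
#' @slot flags character vector of assumption warnings (empty when
#'   synchronicity/stationarity hold and all six are defined).
#' @export
setClass("CrossLaggedResult",
  representation(r = "numeric", p = "numeric", significant = "logical",
    alpha = "numeric", n = "integer", flags = "character"))
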