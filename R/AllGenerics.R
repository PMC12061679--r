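#' Access the voxel data of a volume-like object
#'
#' @param x an [ImageVolume-class], [LabelMap-class] or
#'   [DisplacementField-class].
#' @return the underlying array (3D for volumes, 4D for fields).
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname imgData
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname imgData
#' @export
setMethod("imgData", "DisplacementField", function(x) x@vectors)

#' Voxel spacing in mm
#' @param x a volume-like object.
#' @return numeric(3) spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' Grid origin in mm (world position of voxel 1,1,1)
#' @param x a volume-like object.
#' @return numeric(3) origin in mm.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname origin
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)

#' @rdname origin
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' Grid dimensions of a volume-like object
#' @param x a volume-like object.
#' @return integer(3) voxels per axis.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridDim
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@data))

#' @rdname gridDim
#' @export
setMethod("gridDim", "DisplacementField", function(x) dim(x@vectors)[1:3])

#' Voxel volume in cubic mm
#' @param x a volume-like object.
#' @return scalar voxel volume (mm^3).
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "ImageVolume", function(x) prod(x@spacing))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "DisplacementField", function(x) prod(x@spacing))

#' Region label table of a LabelMap
#' @param x a [LabelMap-class].
#' @return named integer vector of region labels.
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname labelTable
#' @export
setMethod("labelTable", "LabelMap", function(x) x@labels)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d | spacing %s mm | origin %s mm\n",
      class(object), d[1], d[2], d[3],
      paste(signif(object@spacing, 4), collapse = " x "),
      paste(signif(object@origin, 4), collapse = ", ")))
  v <- object@data[is.finite(object@data)]
  if (length(v))
    cat(sprintf("  values: [%.4g, %.4g], mean %.4g\n",
        min(v), max(v), mean(v)))
  invisible(NULL)
})

setMethod("show", "LabelMap", function(object) {
  callNextMethod()
  if (length(object@labels))
    cat("  labels:", paste(sprintf("%s=%d", names(object@labels),
        object@labels), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3L)^2))
  cat(sprintf(
    "DisplacementField %d x %d x %d | spacing %s mm | max |u| %.3g mm\n",
    d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = " x "),
    max(mag)))
  invisible(NULL)
})

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform (world mm): x -> A x + t\n")
  m <- cbind(object@matrix, object@translation)
  dimnames(m) <- list(NULL, c("A1", "A2", "A3", "t"))
  print(round(m, 5))
  invisible(NULL)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: grid %s @ %s mm CT / %s mm SPECT\n",
    paste(object@gridShape, collapse = "x"),
    paste(signif(object@ctSpacing, 3), collapse = "x"),
    paste(signif(object@spectSpacing, 3), collapse = "x")))
  cat(sprintf(
    "  fSAD %.0f%%, Emph %.0f%%, %d hot spot(s) x%.1f, deformation %.1f mm, noise %s, seed %d\n",
    100 * object@fsadFraction, 100 * object@emphFraction,
    object@nHotspots, object@hotspotAmplitude,
    object@deformationMagnitude, object@noiseModel, object@seed))
  invisible(NULL)
})

setMethod("show", "PhantomTruth", function(object) {
  counts <- tabulate(object@classMap@data[object@classMap@data > 0], 3L)
  cat(sprintf(
    "PhantomTruth: lung %d voxels (Normal %d, fSAD %d, Emph %d), %d hot spot(s)\n",
    sum(counts), counts[1], counts[2], counts[3],
    nrow(object@hotspotCenters)))
  if (length(object@lobarVentilation))
    cat("  lobar ventilation:", paste(sprintf("%s=%.3f",
        names(object@lobarVentilation), object@lobarVentilation),
        collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson r = %.3f (n = %d, two-sided p = %.4g) [%s]\n",
      object@r, object@n, object@p, object@strength))
  invisible(NULL)
})

setMethod("show", "CorrelationMap", function(object) {
  cat(sprintf("CorrelationMap (%s); |r| > 0.7 marked *\n", object@mode))
  m <- matrix(sprintf("%s%.2f", ifelse(object@highlighted, "*", " "),
                      object@r), nrow = nrow(object@r),
              dimnames = dimnames(object@r))
  print(m, quote = FALSE)
  invisible(NULL)
})

setMethod("show", "EFAResult", function(object) {
  cat(sprintf("EFAResult: %d factor(s), %.1f%% of variance\n",
      object@nFactors, object@varianceExplainedPct))
  print(round(object@loadings, 3))
  for (f in names(object@keyVariables))
    cat(sprintf("  %s key (|loading| > %.2g): %s\n", f,
        object@loadingThreshold,
        paste(object@keyVariables[[f]], collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "CrossLaggedResult", function(object) {
  cat(sprintf("Cross-lagged panel (n = %d, one-sided alpha = %.3g)\n",
      object@n, object@alpha))
  tab <- data.frame(r = round(object@r, 3), p = signif(object@p, 3),
                    significant = object@significant)
  print(tab)
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})
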