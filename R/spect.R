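# SPECT tracer-distribution statistics, computed on the tracer volume
# after alignment to the inflated (TLC) CT domain: lobar tracer shares,
# whole-lung heterogeneity (coefficient of variation), and the
# standardized maximum (hot-spot magnitude). All three are invariant to
# global rescaling of the tracer counts, which absorbs differences in
# the amount of tracer inhaled.

#' Lobar tracer-concentration shares
#'
#' @param spectAligned tracer [ImageVolume-class] resampled onto the CT
#'   grid of \code{lobes}.
#' @param lobes [LabelMap-class]; 0 = not lung.
#' @return named numeric of per-lobe percentages of the whole-lung
#'   tracer sum (sums to 100); lobar sums attached as attribute
#'   \code{"sums"}.
#' @export
tcPercent <- function(spectAligned, lobes) {
  stopifnot3(all(gridDim(spectAligned) == gridDim(lobes)),
             "tracer volume and lobes must share a grid")
  labs <- labelTable(lobes)
  sums <- vapply(labs, function(l) sum(spectAligned@data[lobes@data == l]),
                 0)
  total <- sum(sums)
  stopifnot3(total > 0, "zero total tracer counts in the lung")
  out <- 100 * sums / total
  attr(out, "sums") <- sums
  out
}

#' Whole-lung tracer heterogeneity (coefficient of variation)
#'
#' The ratio of the standard deviation to the mean of voxel tracer
#' concentration within the lung mask.
#'
#' @param spectAligned tracer [ImageVolume-class] on the CT grid.
#' @param mask [LabelMap-class]; voxels > 0 are lung.
#' @return scalar CV (dimensionless, >= 0).
#' @examples
#' vol <- ImageVolume(array(c(1, 3), c(2, 1, 1)))
#' msk <- LabelMap(array(1L, c(2, 1, 1)))
#' cvTotal(vol, msk)  # sqrt(2)/2
#' @export
cvTotal <- function(spectAligned, mask) {
  stopifnot3(all(gridDim(spectAligned) == gridDim(mask)),
             "tracer volume and mask must share a grid")
  x <- spectAligned@data[mask@data > 0]
  x <- x[!is.na(x)]
  stopifnot3(length(x) >= 2, "need >= 2 lung voxels")
  m <- mean(x)
  stopifnot3(m > 0, "zero mean tracer concentration")
  stats::sd(x) / m
}

#' Standardized maximum tracer concentration (hot-spot magnitude)
#'
#' Standardization defaults to the maximum voxel value over the lung
#' mean, a dimensionless, rescaling-invariant quantity that equals 1 for
#' a homogeneous field; alternatives are exposed because the hot-spot
#' statistic has no single canonical definition.
#'
#' @param spectAligned tracer [ImageVolume-class] on the CT grid.
#' @param mask [LabelMap-class] lung mask.
#' @param standardization "max/mean" (default), "q999/mean" (99.9th
#'   percentile over mean, robust to single-voxel outliers), or
#'   "max/median".
#' @return scalar (>= 1 for max/mean on a non-negative field).
#' @export
tcMax <- function(spectAligned, mask,
                  standardization = c("max/mean", "q999/mean",
                                      "max/median")) {
  standardization <- match.arg(standardization)
  stopifnot3(all(gridDim(spectAligned) == gridDim(mask)),
             "tracer volume and mask must share a grid")
  x <- spectAligned@data[mask@data > 0]
  x <- x[!is.na(x)]
  stopifnot3(length(x) >= 2, "need >= 2 lung voxels")
  m <- mean(x)
  stopifnot3(m > 0, "zero mean tracer concentration")
  switch(standardization,
    "max/mean" = max(x) / m,
    "q999/mean" = as.numeric(stats::quantile(x, 0.999, names = FALSE)) / m,
    "max/median" = {
      md <- stats::median(x)
      stopifnot3(md > 0, "zero median tracer concentration")
      max(x) / md
    })
}
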