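# Quantitative CT biomarkers: tissue fraction, parametric response
# mapping (fSAD% / Emph%), lobar air-volume-change fractions, airway
# normalization, and summary rows for study tables.

#' Tissue fraction from a HU-calibrated CT volume
#'
#' Treats each voxel as an air/tissue mixture: beta = (HU + 1000) / 1000,
#' clamped to [0, 1], so pure air (-1000 HU) gives 0 and soft tissue
#' (0 HU) gives 1.
#'
#' @param ct [ImageVolume-class] in Hounsfield units.
#' @param mask optional [LabelMap-class]; voxels outside it become NA.
#' @return an [ImageVolume-class] of tissue fractions.
#' @examples
#' v <- ImageVolume(array(c(-1000, -900, 0), c(3, 1, 1)))
#' imgData(tissueFraction(v))  # 0, 0.1, 1
#' @export
tissueFraction <- function(ct, mask = NULL) {
  beta <- pmin(pmax((ct@data + 1000) / 1000, 0), 1)
  if (!is.null(mask)) {
    stopifnot3(all(gridDim(mask) == gridDim(ct)),
               "mask must share the CT grid")
    beta[mask@data <= 0] <- NA_real_
  }
  ImageVolume(beta, ct@spacing, ct@origin)
}

#' Parametric response mapping of a registered CT pair
#'
#' Classifies each lung voxel of the inflated scan against its warped
#' deflated counterpart: emphysema when both fall below their thresholds
#' (default inflated < -950 HU and deflated < -856 HU), functional small
#' airway disease (gas trapping) when only the deflated value is below
#' its threshold, normal otherwise. Percentages are reported per lobe
#' and for the total lung.
#'
#' @param insp inflated-lung [ImageVolume-class] (HU).
#' @param expWarped deflated scan warped onto the inflated grid (HU).
#' @param lobes [LabelMap-class]; 0 = not lung.
#' @param thrInsp,thrExp HU thresholds (defaults -950 / -856).
#' @return data.frame with one row per lobe plus "Total": voxel counts
#'   per class and normalPct / fsadPct / emphPct (percent of region
#'   voxels; the three sum to 100). The per-voxel class map is attached
#'   as attribute \code{"classMap"} (a [LabelMap-class], 1 = Normal,
#'   2 = fSAD, 3 = Emph).
#' @export
prmClassify <- function(insp, expWarped, lobes, thrInsp = -950,
                        thrExp = -856) {
  stopifnot3(all(gridDim(insp) == gridDim(expWarped)) &&
             all(gridDim(insp) == gridDim(lobes)),
             "insp, expWarped and lobes must share a grid")
  lung <- lobes@data > 0L
  stopifnot3(any(lung), "empty lung mask")
  iHU <- insp@data[lung]; eHU <- expWarped@data[lung]
  cls <- rep(1L, length(iHU))
  low <- eHU < thrExp
  cls[low & iHU < thrInsp] <- 3L
  cls[low & iHU >= thrInsp] <- 2L
  lobeOf <- lobes@data[lung]
  regions <- c(names(labelTable(lobes)), "Total")
  labs <- c(labelTable(lobes), Total = NA_integer_)
  rows <- lapply(seq_along(regions), function(i) {
    sel <- if (regions[i] == "Total") rep(TRUE, length(cls))
           else lobeOf == labs[i]
    n <- sum(sel)
    cnt <- tabulate(cls[sel], 3L)
    data.frame(region = regions[i], nVoxels = n, nNormal = cnt[1],
               nFsad = cnt[2], nEmph = cnt[3],
               normalPct = if (n) 100 * cnt[1] / n else NA_real_,
               fsadPct = if (n) 100 * cnt[2] / n else NA_real_,
               emphPct = if (n) 100 * cnt[3] / n else NA_real_)
  })
  out <- do.call(rbind, rows)
  cm <- array(0L, gridDim(insp)); cm[lung] <- cls
  attr(out, "classMap") <- LabelMap(cm, spacing(insp), origin(insp),
      labels = c(Normal = 1L, fSAD = 2L, Emph = 3L))
  out
}

#' Lobar air-volume-change fractions from a registration field
#'
#' Air-volume change per voxel is computed from the Jacobian of the
#' inflation-to-deflation field, optionally combined with the tissue
#' fractions of the CT pair for mass-consistent accounting:
#' with both scans given, \eqn{\Delta V_{air} = v[(1-\beta_{insp}) -
#' J(1-\beta_{exp}^{warped})]} per voxel (v = voxel volume); with the
#' field alone, \eqn{\Delta V_{air} = v(1-J)}, which is identical under
#' exact tissue-mass preservation. Lobar sums are normalized to the
#' whole-lung change (DeltaVairF), and the upper-to-middle-plus-lower
#' ratio is the air shift index between upper and dependent lung.
#'
#' @param field [DisplacementField-class] on the inflated grid (pull-back
#'   into the deflated domain).
#' @param lobes [LabelMap-class] on the same grid.
#' @param insp,expWarped optional HU [ImageVolume-class] pair (expWarped
#'   on the inflated grid) for mass-consistent accounting.
#' @param upperLobes,midLowerLobes lobe names forming the ratio.
#' @return list with \code{lobar} (data.frame: lobe, dVair_mL, dVairF),
#'   \code{uml} (upper over middle+lower ratio) and \code{total_mL}.
#' @export
lobarVentilation <- function(field, lobes, insp = NULL, expWarped = NULL,
                             upperLobes = c("LUL", "RUL"),
                             midLowerLobes = c("LLL", "RML", "RLL")) {
  stopifnot3(all(gridDim(field) == gridDim(lobes)),
             "field and lobes must share a grid")
  v <- voxelVolume(lobes)
  J <- .fieldJacobianArr(field@vectors, field@spacing)
  if (!is.null(insp) && !is.null(expWarped)) {
    bi <- pmin(pmax((insp@data + 1000) / 1000, 0), 1)
    be <- pmin(pmax((expWarped@data + 1000) / 1000, 0), 1)
    dv <- v * ((1 - bi) - J * (1 - be))
  } else {
    dv <- v * (1 - J)
  }
  lung <- lobes@data > 0L
  labs <- labelTable(lobes)
  perLobe <- vapply(labs, function(l) sum(dv[lobes@data == l]), 0)
  total <- sum(perLobe)
  stopifnot3(abs(total) > 1e-9, "zero whole-lung air-volume change")
  frac <- perLobe / total
  denom <- sum(perLobe[names(labs) %in% midLowerLobes])
  uml <- if (abs(denom) > 0)
    sum(perLobe[names(labs) %in% upperLobes]) / denom else NA_real_
  list(lobar = data.frame(lobe = names(labs), dVair_mL = perLobe / 1000,
                          dVairF = frac, row.names = NULL),
       uml = uml, total_mL = total / 1000)
}

#' Normalize airway measurements against healthy-predicted values
#'
#' The normalized hydraulic diameter and wall thickness are the relative
#' deviations from the value predicted for a healthy subject of the same
#' sex, age and height: \code{dhStar = |dh - dhPred| / dhPred}, and
#' analogously for wall thickness. Records without predicted values are
#' flagged \code{excluded} and left NA.
#'
#' @param record data.frame with columns \code{site}, \code{dh},
#'   \code{wt}, \code{dhPred}, \code{wtPred} (mm; NA allowed in the
#'   predictions).
#' @return the data.frame with added \code{dhStar}, \code{wtStar},
#'   \code{excluded}.
#' @export
normalizeAirway <- function(record) {
  need <- c("site", "dh", "wt", "dhPred", "wtPred")
  stopifnot3(all(need %in% names(record)),
             paste("record needs columns:", paste(need, collapse = ", ")))
  bad <- (!is.na(record$dhPred) & record$dhPred <= 0) |
         (!is.na(record$wtPred) & record$wtPred <= 0)
  if (any(bad))
    stop("non-positive predicted value for site(s): ",
         paste(record$site[bad], collapse = ", "), call. = FALSE)
  record$excluded <- is.na(record$dhPred) | is.na(record$wtPred)
  record$dhStar <- ifelse(record$excluded, NA_real_,
                          abs(record$dh - record$dhPred) / record$dhPred)
  record$wtStar <- ifelse(record$excluded, NA_real_,
                          abs(record$wt - record$wtPred) / record$wtPred)
  record
}

#' Mean and SD of a study-table variable at one visit
#'
#' Reproduces the "Mean +/- SD" summary rows of the study tables.
#' The default \code{ddof = 0} (population SD) matches the convention of
#' the printed tables; set \code{ddof = 1} for the sample SD.
#'
#' @param table tidy data.frame with columns \code{subject},
#'   \code{visit}, and the variables.
#' @param variable variable (column) name.
#' @param visit visit label (e.g. "V0").
#' @param ddof degrees-of-freedom correction for the SD.
#' @return named numeric: \code{mean}, \code{sd}, \code{n}.
#' @export
summarizeTable <- function(table, variable, visit, ddof = 0) {
  stopifnot3(variable %in% names(table), paste("no column", variable))
  x <- table[[variable]][table$visit == visit]
  x <- x[!is.na(x)]
  stopifnot3(length(x) >= 2, "need >= 2 non-missing values")
  m <- mean(x)
  c(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - ddof)),
    n = length(x))
}
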