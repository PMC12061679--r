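# NIfTI input/output. Volumes round-trip through RNifti; the grid origin
# is carried in the sform (diagonal spacing, no rotation), which is all
# the phantom and study pipelines need.

#' Read a volume or displacement field from a NIfTI file
#'
#' 3D files become [ImageVolume-class] objects; 4D files with a trailing
#' dimension of 3 become [DisplacementField-class] objects.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return an ImageVolume or DisplacementField.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  sp <- abs(diag(xf[1:3, 1:3, drop = FALSE]))
  if (any(sp == 0)) sp <- RNifti::pixdim(img)[1:3]
  org <- xf[1:3, 4]
  a <- as.array(img)
  a <- array(as.numeric(a), dim(a))
  if (length(dim(a)) == 4L && dim(a)[4] == 3L)
    DisplacementField(a, spacing = sp, origin = org)
  else if (length(dim(a)) == 3L)
    ImageVolume(a, spacing = sp, origin = org)
  else stop("unsupported NIfTI dimensionality: ",
            paste(dim(a), collapse = "x"))
}

#' Write a volume or displacement field to a NIfTI file
#'
#' @param x an [ImageVolume-class], [LabelMap-class] (written as integer
#'   labels) or [DisplacementField-class] (written as a 4D volume).
#' @param path output file name (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  a <- if (is(x, "DisplacementField")) x@vectors else x@data
  sp <- spacing(x); org <- origin(x)
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rep(sp, length.out = length(dim(a)))[1:3]
  xf <- rbind(cbind(diag(sp), org), c(0, 0, 0, 1))
  attr(xf, "code") <- 2L
  RNifti::sform(img) <- xf
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an affine transform as a plain-text 4x4 matrix file
#'
#' @param x an [AffineTransform-class].
#' @param path output text file.
#' @return the path, invisibly.
#' @export
writeAffine <- function(x, path) {
  m <- rbind(cbind(x@matrix, x@translation), c(0, 0, 0, 1))
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an affine transform from a plain-text 4x4 matrix file
#'
#' @param path text file holding a 4x4 matrix.
#' @return an [AffineTransform-class].
#' @export
readAffine <- function(path) {
  m <- unname(as.matrix(utils::read.table(path)))
  stopifnot3(all(dim(m) == c(4L, 4L)), "expected a 4x4 matrix file")
  AffineTransform(m[1:3, 1:3], m[1:3, 4])
}
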