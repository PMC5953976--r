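#' Read an SUV volume from a NIfTI-1 file
#'
#' The voxel values are taken as-is (they must already be in SUV units).
#' Only affines that are pure axis-aligned scaling plus translation are
#' accepted; any rotation, shear or axis flip is rejected with an error,
#' because the package's voxel-centre geometry assumes `position =
#' origin + (index - 1) * spacing` along each axis.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [suv_image()].
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3L)
    stop("NIfTI volume must be 3-D", call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("NIfTI affine is not axis-aligned (rotation/shear present); ",
         "resample or reorient the volume before loading", call. = FALSE)
  if (any(diag(rot) <= 0))
    stop("NIfTI affine has non-positive axis scaling (flipped axes); ",
         "reorient the volume before loading", call. = FALSE)
  suv_image(arr, spacing = diag(rot), origin = xf[1:3, 4])
}

#' Write an SUV volume to a NIfTI-1 file
#'
#' Writes the image with a diagonal affine `diag(spacing)` and translation
#' `origin`, so it round-trips exactly through [read_suv_nifti()].
#'
#' @param image an [suv_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_suv_nifti <- function(image, path) {
  stop_if_not_image(image)
  nif <- RNifti::asNifti(image$values)
  RNifti::pixdim(nif) <- image$spacing
  aff <- rbind(cbind(diag(image$spacing), image$origin), c(0, 0, 0, 1))
  aff <- structure(aff, code = 2L)
  nif <- RNifti::`sform<-`(nif, aff)
  nif <- RNifti::`qform<-`(nif, aff)
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' Write a binary mask or label map as NIfTI on an image's grid
#'
#' @param mask logical or integer array congruent with `image`.
#' @param image the parent [suv_image()] supplying the grid geometry.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, image, path) {
  check_congruent(mask, image)
  arr <- array(as.integer(mask), dim(image$values))
  write_suv_nifti(suv_image(arr, image$spacing, image$origin), path)
}
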