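# NIfTI-1 reading/writing via RNifti.  On disk the array is stored in the
# conventional (column, row, slice) order with pixdim (col mm, row mm,
# slice mm); in memory everything uses the package's (z, row, column)
# convention, so this file is the single conversion point.

#' Read a NIfTI volume or mask
#'
#' Reads a single-channel 3D NIfTI-1 image.  Images whose values are all in
#' `{0, 1}` are returned as a [binary_mask()]; anything else is returned as a
#' [ct_volume()] with values clamped to the HU range \[-1024, 3071\].
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as `"auto"` (default), `"volume"`, or `"mask"`.
#' @param label mask label used when a mask is returned.
#' @return A [ct_volume()] or [binary_mask()].
#' @export
read_nifti <- function(path, as = c("auto", "volume", "mask"),
                       label = "mask") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(img, dim = d[1:3]); d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a single-channel 3D image (dims: %s)",
                 path, paste(dim(img), collapse = "x")))
  pd <- RNifti::pixdim(img)[1:3]
  vox <- aperm(array(as.numeric(img), dim = d), c(3, 2, 1))  # (z, row, col)
  spacing <- c(pd[2], pd[1], pd[3])                          # (row, col, slice)
  is_binary <- all(vox %in% c(0, 1))
  if (as == "mask" || (as == "auto" && is_binary)) {
    if (!is_binary)
      stop(sprintf("'%s' requested as mask but contains values outside {0,1}", path))
    binary_mask(vox, label = label, spacing = spacing)
  } else {
    ct_volume(vox, spacing = spacing)
  }
}

#' Write a volume or mask as NIfTI
#'
#' Volumes are stored as 64-bit floats (lossless for HU values including
#' fractional noise); masks as unsigned 8-bit integers.  Grid, spacing and
#' values round-trip exactly through [read_nifti()].
#'
#' @param x a [ct_volume()] or [binary_mask()].
#' @param path output file, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "ct_volume")) {
    vox <- x$voxels; datatype <- "double"
  } else if (inherits(x, "binary_mask")) {
    vox <- x$voxels; datatype <- "uint8"
  } else stop("`x` must be a ct_volume or binary_mask")
  arr <- aperm(vox, c(3, 2, 1))  # (col, row, z) on disk
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(x$spacing[2], x$spacing[1], x$spacing[3])
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
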