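#' CT volume in Hounsfield units
#'
#' The common substrate of every pipeline stage: a 3D scalar field in
#' Hounsfield units (HU) on a regular anisotropic grid.  The internal axis
#' convention, used by every module of this package, is `(z, row, column)`
#' with `z` increasing inferior to superior; axial slices are
#' `volume$voxels[z, , ]`.  Physical distances are obtained by multiplying
#' 0-based index deltas by `spacing`.
#'
#' @param voxels 3D numeric array, dimensions `(n_slices, rows, columns)`.
#' @param spacing numeric length-3, `(row mm, column mm, slice mm)`, all
#'   strictly positive.
#' @param clamp clamp voxel values into the representable HU range
#'   \[-1024, 3071\] (the default, applied after reading any external file).
#' @return An object of class `ct_volume` with fields `voxels`, `spacing`,
#'   `slice_shape`.
#' @export
ct_volume <- function(voxels, spacing, clamp = TRUE) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, row, column)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (row, column, slice mm)")
  if (clamp) voxels <- pmin(pmax(voxels, -1024), 3071)
  structure(
    list(voxels = voxels, spacing = spacing,
         slice_shape = dim(voxels)[2:3]),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices of %d x %d, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary 3D segmentation mask
#'
#' A `{0,1}` label field on the same `(z, row, column)` grid as its companion
#' [ct_volume()], one per anatomical structure.
#'
#' @param voxels 3D array coercible to logical; stored as integer 0/1.
#' @param label structure name, one of `"spine"`, `"lumen"`, `"thrombus"`
#'   (free text permitted for derived masks).
#' @param spacing physical spacing inherited from the companion volume.
#' @return An object of class `binary_mask` with fields `voxels` (integer
#'   0/1 array), `label`, `spacing`.
#' @export
binary_mask <- function(voxels, label = "mask", spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, row, column)")
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers")
  structure(list(voxels = v, label = label, spacing = spacing),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask '%s'> %d x %d x %d, %d foreground voxels\n",
              x$label, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

#' @keywords internal
mask_array <- function(x) {
  if (inherits(x, "binary_mask")) x$voxels
  else if (is.array(x)) array(as.integer(x != 0), dim = dim(x))
  else stop("expected a binary_mask or an array")
}

#' @keywords internal
check_same_grid <- function(a, b, what = "inputs") {
  da <- if (is.list(a)) dim(a$voxels) else dim(a)
  db <- if (is.list(b)) dim(b$voxels) else dim(b)
  if (!identical(da, db))
    stop(sprintf("%s are on different grids: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}
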