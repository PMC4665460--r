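#' Voxel image container
#'
#' A minimal 3-D scalar image carrier shared by simulated PET (Bq/mL) and CT
#' (unitless contrast index) volumes. Voxel centers sit at
#' `origin + (index - 1 + 0.5) * spacing` per axis (1-based indices); coronal
#' planes are fixed-y slices.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric(3), voxel edge lengths in mm; all > 0.
#' @param origin numeric(3), position (mm) of the grid corner (not the first
#'   voxel center).
#' @param units one of `"Bq_per_mL"`, `"contrast_index"`, `"label"`.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, spacing, origin = c(0, 0, 0),
                        units = c("Bq_per_mL", "contrast_index", "label")) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  if (any(!is.finite(data)))
    stop("'data' contains non-finite values")
  structure(
    list(data = data, spacing = spacing, origin = origin, units = units),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "voxel_image: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm [%s]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$units))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume of an image
#'
#' @param img a [voxel_image].
#' @param units `"uL"` (= mm^3) or `"mL"`.
#' @return Scalar voxel volume.
#' @export
voxel_volume <- function(img, units = c("uL", "mL")) {
  units <- match.arg(units)
  v <- prod(img$spacing)            # mm^3 == uL exactly
  if (units == "mL") v / 1000 else v
}

#' Voxel center coordinates along one axis
#'
#' @param img a [voxel_image].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel center positions (mm).
#' @export
voxel_centers <- function(img, axis) {
  n <- dim(img$data)[axis]
  img$origin[axis] + (seq_len(n) - 0.5) * img$spacing[axis]
}

#' Read / write voxel images as NIfTI
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()]; spacing
#' is carried in the NIfTI pixdim and units in an attribute-free convention
#' (the caller states them on read).
#'
#' @param img a [voxel_image].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units units to stamp on the image read back.
#' @return `write_voxel_image` returns `path` invisibly; `read_voxel_image`
#'   returns a [voxel_image].
#' @export
write_voxel_image <- function(img, path) {
  nim <- RNifti::asNifti(img$data, reference = NULL)
  nim <- RNifti::`pixdim<-`(nim, img$spacing)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname write_voxel_image
#' @export
read_voxel_image <- function(path, units = "Bq_per_mL") {
  nim <- RNifti::readNifti(path)
  voxel_image(array(as.numeric(nim), dim = dim(nim)),
              spacing = RNifti::pixdim(nim)[1:3], units = units)
}
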