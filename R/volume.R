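#' CT and mask volume containers
#'
#' Light wrappers around 3D numeric arrays carrying voxel spacing (mm) and a
#' world-space origin. A `ct_volume` holds calibrated Hounsfield-unit values;
#' a `mask_volume` holds a binary (0/1) segmentation on the same grid.
#'
#' @param values 3D numeric array. For masks, every value must be 0 or 1.
#' @param spacing Positive length-3 numeric, voxel edge lengths in mm.
#' @param origin Length-3 numeric world coordinate of voxel (1,1,1).
#' @return An object of class `ct_volume` or `mask_volume`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(is.finite(values))) stop("CT values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
mask_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (!all(values %in% c(0, 1)))
    stop("mask values must all be 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  storage.mode(values) <- "integer"
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "mask_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; HU range [", round(min(x$values), 1), ", ",
      round(max(x$values), 1), "]\n", sep = "")
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat("<mask_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm; ", sum(x$values), " foreground voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
dim.mask_volume <- function(x) dim(x$values)

#' Read and write volumes as NIfTI
#'
#' I/O goes through the NIfTI-1 format; spacing and origin are carried in the
#' header (pixdim and the sform offset).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` a `ct_volume`; `read_mask()` a `mask_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D volume: ", path)
  ct_volume(vals, spacing = RNifti::pixdim(img)[1:3],
            origin = -RNifti::origin(img))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D volume: ", path)
  if (!all(vals %in% c(0, 1)))
    stop("mask file contains values outside {0, 1}: ", path)
  mask_volume(vals, spacing = RNifti::pixdim(img)[1:3],
              origin = -RNifti::origin(img))
}

#' @param vol A `ct_volume`, `mask_volume`, or `habitat_map`.
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  vals <- vol$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that an image and mask share a grid
#'
#' @param vol A `ct_volume`.
#' @param mask A `mask_volume`.
#' @keywords internal
check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$values), dim(mask$values)))
    stop("image and mask grids differ: ",
         paste(dim(vol$values), collapse = "x"), " vs ",
         paste(dim(mask$values), collapse = "x"))
  if (max(abs(vol$spacing - mask$spacing)) > 1e-6)
    stop("image and mask voxel spacings differ")
  invisible(TRUE)
}

#' Crop an image/mask pair to the mask bounding box plus a margin
#'
#' @param margin Margin in voxels added on each side.
#' @return List with cropped `vol` and `mask`.
#' @keywords internal
crop_to_mask <- function(vol, mask, margin = 2L) {
  check_aligned(vol, mask)
  w <- which(mask$values == 1L, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("mask is empty")
  d <- dim(mask$values)
  lo <- pmax(apply(w, 2, min) - margin, 1L)
  hi <- pmin(apply(w, 2, max) + margin, d)
  v <- vol$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m <- mask$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(vol = ct_volume(v, vol$spacing, vol$origin),
       mask = mask_volume(m, mask$spacing, mask$origin))
}
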