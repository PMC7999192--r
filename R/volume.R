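#' Density volume container
#'
#' A `density_volume` is a 3-D scalar voxel grid with physical spacing and
#' origin, the common currency between the phantom generator, the acquisition
#' simulator and the segmentation step.  The axis convention is fixed across
#' the package: axis 1 is mediolateral (x), axis 2 anteroposterior (y,
#' anterior positive), axis 3 craniocaudal (z, cranial positive).  Voxel
#' centres sit at `origin + index * spacing` with 0-based indices, all in mm.
#'
#' @param voxels numeric 3-D array of density values (arbitrary units).
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin numeric length-3, world position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `density_volume`.
#' @export
density_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop_condylometry("voxels must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_condylometry("spacing must be positive and finite on all axes")
  if (any(!is.finite(voxels)))
    stop_condylometry("volume contains non-finite values")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<density_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              min(x$voxels), max(x$voxels),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.density_volume <- function(x) dim(x$voxels)

#' @rdname density_volume
#' @param x a `density_volume`.
#' @param ... unused.
#' @export
as.array.density_volume <- function(x, ...) x$voxels

# world coordinates of voxel centres along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$voxels)[axis]) - 1) * vol$spacing[axis]
}

#' Read and write density volumes as NIfTI-1
#'
#' Volumes are stored as NIfTI-1 (`.nii` / `.nii.gz`) with the voxel spacing
#' in `pixdim` and the origin in an axis-aligned qform.  Only axis-aligned
#' volumes are supported; reading an obliquely oriented image is an error.
#'
#' @param vol a [density_volume()].
#' @param file path to a `.nii` or `.nii.gz` file.
#' @return `read_volume` returns a [density_volume()]; `write_volume`
#'   invisibly returns `file`.
#' @export
write_volume <- function(vol, file) {
  stopifnot(inherits(vol, "density_volume"))
  im <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(im) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::`qform<-`(im, structure(m, code = 2L)) -> im
  RNifti::writeNifti(im, file)
  invisible(file)
}

#' @rdname write_volume
#' @export
read_volume <- function(file) {
  im <- RNifti::readNifti(file)
  arr <- as.array(im)
  if (length(dim(arr)) != 3L)
    stop_condylometry("expected a 3-D NIfTI volume")
  m <- RNifti::xform(im)
  rot <- m[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop_condylometry("only axis-aligned NIfTI volumes are supported")
  density_volume(arr, spacing = abs(diag(rot)), origin = m[1:3, 4])
}

#' Binary bone model
#'
#' The 1-bit model produced by [segment()]: a boolean mask on the voxel grid
#' together with the global threshold that produced it.  Exactly one
#' 26-connected component is retained.
#'
#' @param mask logical 3-D array.
#' @param spacing,origin grid geometry as in [density_volume()].
#' @param threshold_used the global threshold (density units) that produced
#'   the mask.
#' @return An object of class `binary_model`.
#' @export
binary_model <- function(mask, spacing, origin = c(0, 0, 0),
                         threshold_used = NA_real_) {
  if (length(dim(mask)) != 3L) stop_condylometry("mask must be a 3-D array")
  if (!any(mask)) stop_condylometry("binary model has no foreground voxels")
  structure(list(mask = mask, spacing = rep_len(as.numeric(spacing), 3L),
                 origin = rep_len(as.numeric(origin), 3L),
                 threshold_used = threshold_used),
            class = "binary_model")
}

#' @export
print.binary_model <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf(
    "<binary_model> %d x %d x %d voxels, %d foreground, threshold %.4g\n",
    d[1], d[2], d[3], sum(x$mask), x$threshold_used))
  invisible(x)
}

#' @rdname binary_model
#' @param model a `binary_model`.
#' @param file path to a `.nii`/`.nii.gz` file (written as uint8).
#' @export
write_binary_model <- function(model, file) {
  stopifnot(inherits(model, "binary_model"))
  vol <- density_volume(array(as.numeric(model$mask), dim(model$mask)),
                        model$spacing, model$origin)
  write_volume(vol, file)
}
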