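#' Calibrated image stack for one imaging region
#'
#' Container for a 3D fluorescence volume. `voxels` is a numeric array
#' indexed `(slice, row, column)`; array slice 1 is z index 0, the base
#' (membrane-proximal) plane from which FLS grow. Intensities are arbitrary
#' units, stored as non-negative integer-valued counts in 0..65535 so stacks
#' round-trip exactly through 16-bit TIFF.
#'
#' @param voxels numeric 3D array `(slice, row, column)`, non-negative.
#' @param pixel_size_xy lateral calibration, um per pixel (> 0).
#' @param z_step axial calibration, um per slice (> 0).
#' @param region_id identifier of the imaging region.
#' @param condition condition label (e.g. an scFv name or `"C"` for control).
#' @param actin_state `"none_added"` or `"actin_added"`.
#' @return An object of class `fls_stack`.
#' @export
fls_stack <- function(voxels, pixel_size_xy, z_step,
                      region_id = "region", condition = "C",
                      actin_state = c("none_added", "actin_added")) {
  actin_state <- match.arg(actin_state)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("'voxels' must be a 3D array indexed (slice, row, column)")
  }
  if (dim(voxels)[1] < 1L) stop("stack must contain at least one slice")
  if (any(voxels < 0)) stop("voxel intensities must be non-negative")
  if (!is.numeric(pixel_size_xy) || pixel_size_xy <= 0) {
    stop("'pixel_size_xy' must be a positive calibration (um/px)")
  }
  if (!is.numeric(z_step) || z_step <= 0) {
    stop("'z_step' must be a positive calibration (um/slice)")
  }
  structure(
    list(
      voxels = voxels,
      pixel_size_xy = pixel_size_xy,
      z_step = z_step,
      region_id = region_id,
      condition = condition,
      actin_state = actin_state
    ),
    class = "fls_stack"
  )
}

#' @export
print.fls_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<fls_stack> %d slices x %d x %d px | %.3g um/px, %.3g um/slice | region %s (%s, %s)\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step,
    x$region_id, x$condition, x$actin_state
  ))
  invisible(x)
}

#' Number of z-slices in a stack
#' @param stack an [fls_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) {
  stopifnot(inherits(stack, "fls_stack"))
  dim(stack$voxels)[1]
}

# Extract slice z (0-based) as a matrix (row, column).
stack_slice <- function(stack, z) {
  stack$voxels[z + 1L, , , drop = TRUE]
}

#' Write a stack as a multi-page 16-bit grayscale TIFF
#'
#' One page per z-slice, page order = z order (page 1 is the base slice).
#' Intensities must already be integer counts in 0..65535; they are stored
#' losslessly, so `read_stack(write_stack(s))` reproduces `s$voxels` exactly.
#'
#' @param stack an [fls_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fls_stack"))
  v <- stack$voxels
  if (any(v != round(v)) || any(v > 65535)) {
    stop("voxels must be integer counts in 0..65535 for 16-bit TIFF output")
  }
  pages <- lapply(seq_len(dim(v)[1]), function(i) v[i, , , drop = TRUE] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages become z-slices in file order; page 1 is the base slice (z = 0).
#' Sample values are promoted to counts in 0..65535. Calibration always
#' comes from the arguments; if the file carries a conflicting resolution
#' tag a warning is emitted and the argument wins.
#'
#' @param path TIFF file path.
#' @param pixel_size_xy,z_step calibration in um/px and um/slice.
#' @param region_id,condition,actin_state region metadata, see [fls_stack()].
#' @return An [fls_stack()].
#' @export
read_stack <- function(path, pixel_size_xy, z_step,
                       region_id = "region", condition = "C",
                       actin_state = "none_added") {
  if (!file.exists(path)) {
    stop(sprintf("stack file '%s' does not exist or is unreadable", path))
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop(sprintf("failed to parse '%s' as TIFF: %s", path, conditionMessage(e)))
  )
  if (length(pages) == 0L) stop(sprintf("TIFF '%s' contains zero pages", path))
  if (length(dim(pages[[1]])) == 3L) {
    stop(sprintf("TIFF '%s' is RGB/multi-channel; only grayscale stacks are supported", path))
  }
  res <- attr(pages[[1]], "x.resolution")
  unit <- attr(pages[[1]], "resolution.unit")
  if (!is.null(res) && !is.null(unit) && identical(unit, "micron")) {
    file_px <- 1 / res
    if (abs(file_px - pixel_size_xy) > 1e-9) {
      warning(sprintf(
        "TIFF resolution tag implies %.4g um/px but configuration says %.4g um/px; using the configured value",
        file_px, pixel_size_xy
      ))
    }
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(nz)) vox[i, , ] <- round(pages[[i]] * 65535)
  fls_stack(vox, pixel_size_xy, z_step,
    region_id = region_id, condition = condition, actin_state = actin_state
  )
}
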