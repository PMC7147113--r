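# Per-slice detection of FLS cross-sections: difference-of-Gaussians
# band-pass, adaptive global threshold, 8-connected components.

#' Segmentation parameters
#'
#' @param sigma_small,sigma_large standard deviations (px) of the two
#'   Gaussians of the band-pass, `0 < sigma_small < sigma_large`. The
#'   defaults (1.5, 3) tune the filter to cross-sections ~0.3-0.6 um in
#'   diameter at 0.1 um/px.
#' @param k threshold stringency: a pixel is foreground when its filter
#'   response exceeds `mean + k * sd` of the whole slice (population sd).
#' @param min_area_px minimum component area. The default 12 px sits above
#'   the typical area of correlated-noise blobs that survive thresholding of
#'   the smoothed response (a few px at these sigmas) and far below the
#'   smallest genuine cross-section (~30 px for a 0.25 um shaft radius at
#'   0.1 um/px).
#' @return A validated list of class `fls_seg_config`.
#' @export
seg_config <- function(sigma_small = 1.5, sigma_large = 3, k = 3,
                       min_area_px = 12L) {
  if (!is.numeric(sigma_small) || !is.numeric(sigma_large) ||
    sigma_small <= 0 || sigma_large <= sigma_small) {
    stop("need 0 < sigma_small < sigma_large")
  }
  if (k < 0) stop("'k' must be >= 0")
  if (min_area_px < 1L) stop("'min_area_px' must be >= 1")
  structure(
    list(
      sigma_small = sigma_small, sigma_large = sigma_large,
      k = k, min_area_px = as.integer(min_area_px)
    ),
    class = "fls_seg_config"
  )
}

#' 2D difference-of-Gaussians filter
#'
#' Returns `G(sigma_small) * I - G(sigma_large) * I` where `*` is 2D
#' convolution with reflective (symmetric, edge-duplicating) boundary
#' handling and kernels truncated at 4 sigma. The operation is linear in the
#' input and maps constant images to zero.
#'
#' @param slice_image 2D numeric matrix.
#' @param sigma_small,sigma_large Gaussian sds in px, `0 < small < large`.
#' @return Matrix of the same shape as the input.
#' @export
dog_filter <- function(slice_image, sigma_small = 1.5, sigma_large = 3) {
  if (!is.matrix(slice_image)) stop("'slice_image' must be a 2D matrix")
  if (sigma_small <= 0 || sigma_large <= sigma_small) {
    stop("need 0 < sigma_small < sigma_large")
  }
  blur_reflect(slice_image, sigma_small) - blur_reflect(slice_image, sigma_large)
}

#' Threshold a filtered slice at mean + k sd
#'
#' Statistics are computed over the whole slice with the population sd
#' (divisor n). Increasing `k` never adds pixels.
#'
#' @param filtered_image 2D numeric matrix (typically a [dog_filter()]
#'   response).
#' @param k non-negative stringency multiplier.
#' @return Logical matrix; `TRUE` marks foreground.
#' @export
threshold_slice <- function(filtered_image, k = 3) {
  if (!is.matrix(filtered_image) || length(filtered_image) == 0L) {
    stop("'filtered_image' must be a non-empty 2D matrix")
  }
  if (k < 0) stop("'k' must be >= 0")
  filtered_image > (mean(filtered_image) + k * sd_pop(filtered_image))
}

#' Extract 8-connected components from a binary mask
#'
#' Components smaller than `min_area_px` are discarded. Centroids are
#' intensity-weighted means of the member pixel coordinates when
#' `intensity_image` is supplied (the original, unfiltered slice), otherwise
#' unweighted. Coordinates are 0-based with (x, y) = (column, row).
#' Components are ordered by (centroid y, centroid x).
#'
#' @param binary_mask logical or 0/1 matrix.
#' @param slice_index 0-based z index recorded on every component.
#' @param min_area_px minimum pixel count (>= 1).
#' @param intensity_image optional matrix of the same shape used for
#'   centroid weighting and mean intensity.
#' @return A data.frame with one row per component: `slice`, `cx`, `cy`,
#'   `area_px`, `mean_intensity`, and a list-column `pixels` of `n x 2`
#'   matrices of 0-based (x, y) member coordinates.
#' @export
extract_components <- function(binary_mask, slice_index, min_area_px = 12L,
                               intensity_image = NULL) {
  if (!is.matrix(binary_mask)) stop("'binary_mask' must be a matrix")
  if (!all(binary_mask %in% c(0, 1, TRUE, FALSE))) {
    stop("'binary_mask' must be binary")
  }
  empty <- data.frame(
    slice = integer(0), cx = numeric(0), cy = numeric(0),
    area_px = integer(0), mean_intensity = numeric(0)
  )
  empty$pixels <- list()
  lab <- label8(binary_mask)
  if (max(lab) == 0L) {
    return(empty)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  keep_tab <- table(labs)
  keep <- as.integer(names(keep_tab)[keep_tab >= min_area_px])
  if (length(keep) == 0L) {
    return(empty)
  }
  rows <- lapply(keep, function(l) {
    px <- idx[labs == l, , drop = FALSE] # (row, col), 1-based
    w <- if (is.null(intensity_image)) {
      rep(1, nrow(px))
    } else {
      intensity_image[px]
    }
    if (sum(w) == 0) w <- rep(1, nrow(px))
    x <- px[, 2] - 1
    y <- px[, 1] - 1
    d <- data.frame(
      slice = as.integer(slice_index),
      cx = sum(w * x) / sum(w),
      cy = sum(w * y) / sum(w),
      area_px = nrow(px),
      mean_intensity = if (is.null(intensity_image)) NA_real_ else mean(intensity_image[px])
    )
    d$pixels <- list(cbind(x = x, y = y))
    d
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cy, out$cx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment every slice of a stack
#'
#' Applies [dog_filter()], [threshold_slice()] and [extract_components()]
#' independently to each z-slice; centroids are weighted by the original
#' (unfiltered) slice intensities.
#'
#' @param stack an [fls_stack()].
#' @param config a [seg_config()].
#' @return A list of length `n_slices(stack)`; element `z + 1` holds the
#'   component data.frame of z index `z` (see [extract_components()]).
#' @export
segment_stack <- function(stack, config = seg_config()) {
  stopifnot(inherits(stack, "fls_stack"), inherits(config, "fls_seg_config"))
  nz <- n_slices(stack)
  out <- vector("list", nz)
  for (z in 0:(nz - 1L)) {
    sl <- stack_slice(stack, z)
    comps <- tryCatch(
      {
        filt <- dog_filter(sl, config$sigma_small, config$sigma_large)
        mask <- threshold_slice(filt, config$k)
        extract_components(mask, z, config$min_area_px, intensity_image = sl)
      },
      error = function(e) {
        stop(sprintf("segmentation failed at slice %d: %s", z, conditionMessage(e)))
      }
    )
    out[[z + 1L]] <- comps
  }
  names(out) <- paste0("z", 0:(nz - 1L))
  out
}
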