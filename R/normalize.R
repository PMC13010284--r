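#' Mode of the brain-masked intensity histogram
#'
#' Bins the intensities of voxels inside the brain mask into `n_bins`
#' equal-width bins spanning their `[min, max]` range and returns the center
#' of the most populated bin. Ties are broken toward the lower-intensity
#' bin. A constant volume inside the mask (degenerate single-value
#' histogram) returns that constant.
#'
#' @param volume raw 3D intensity volume
#' @param brain_mask binary volume on the same grid (nonzero = brain)
#' @param n_bins number of equal-width bins (default 256)
#' @return the mode-bin center, a positive scalar
#' @export
brain_histogram_mode <- function(volume, brain_mask, n_bins = 256L) {
  check_same_grid(volume, brain_mask, "volume and brain_mask")
  v <- as.numeric(volume)[as.logical(brain_mask != 0)]
  if (length(v) == 0L) stop("brain_mask is empty: cannot compute a histogram mode")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    mode_value <- lo
  } else {
    width <- (hi - lo) / n_bins
    idx <- pmin(floor((v - lo) / width), n_bins - 1)  # top edge joins last bin
    counts <- tabulate(idx + 1L, nbins = n_bins)
    k <- which.max(counts)                            # first max = lower bin
    mode_value <- lo + (k - 0.5) * width
  }
  if (mode_value <= 0)
    stop("histogram mode is non-positive; intensity normalization is undefined")
  mode_value
}

#' Mode-anchored 8-bit intensity normalization
#'
#' Maps each voxel `v` to `min(v * 75 / mode_value, 255)`: the histogram
#' mode of brain tissue is pinned to 75 on a 0-255 dynamic range, which
#' removes arbitrary per-institution global intensity scales without
#' observing any other subject. Applied to the full (non-skull-stripped)
#' volume; negative inputs clamp to 0. Values remain continuous — 8-bit
#' quantization happens only at image export.
#'
#' @param volume raw 3D intensity volume
#' @param mode_value positive scalar, usually from [brain_histogram_mode()]
#' @param modality optional label ("t1w", "t2w", "t1gd")
#' @return a `normalized_volume`: the scaled volume with attributes
#'   `mode_value` and `modality`
#' @export
normalize_intensity <- function(volume, mode_value, modality = NULL) {
  if (!is.numeric(mode_value) || length(mode_value) != 1L || mode_value <= 0)
    stop("mode_value must be a single positive number")
  out <- pmin(pmax(as.numeric(volume) * 75 / mode_value, 0), 255)
  dim(out) <- dim(volume)
  out <- as_volume(out, voxel_size(volume))
  attr(out, "mode_value") <- mode_value
  attr(out, "modality") <- modality
  class(out) <- c("normalized_volume", class(out))
  out
}

#' Normalize one MRI modality end to end
#'
#' Convenience wrapper: computes the 256-bin brain-histogram mode and
#' applies [normalize_intensity()].
#'
#' @inheritParams brain_histogram_mode
#' @inheritParams normalize_intensity
#' @return a `normalized_volume`
#' @export
normalize_mri <- function(volume, brain_mask, n_bins = 256L, modality = NULL) {
  normalize_intensity(volume, brain_histogram_mode(volume, brain_mask, n_bins),
                      modality = modality)
}
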