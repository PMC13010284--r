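#' Cerebellum-referenced tumor-to-normal (T/N) PET normalization
#'
#' Divides every voxel of the PET SUV volume by the mean SUV inside the
#' cerebellum mask, converting uptake to a tumor-to-normal-tissue ratio —
#' independent of injected dose and scanner scale. The 8-bit target
#' encoding multiplies T/N by 51 and ceilings at 255 (T/N 5 saturates).
#'
#' @param pet_suv PET volume in SUV units
#' @param cerebellum_mask binary reference-region mask on the same grid
#' @return a `tn_volume`: list with `tn_values`, `encoded` (0-255, clipped),
#'   `cerebellum_mean_suv`
#' @export
tn_normalize <- function(pet_suv, cerebellum_mask) {
  if (is.null(cerebellum_mask))
    stop("cerebellum_mask is missing: no reference region")
  check_same_grid(pet_suv, cerebellum_mask, "PET and cerebellum_mask")
  keep <- as.logical(cerebellum_mask != 0)
  if (!any(keep)) stop("cerebellum_mask is empty: no reference region")
  ref <- mean(as.numeric(pet_suv)[keep])
  if (ref <= 0) stop("non-positive mean cerebellar SUV; T/N undefined")
  tn <- as.numeric(pet_suv) / ref
  dim(tn) <- dim(pet_suv)
  vs <- voxel_size(pet_suv)
  enc <- pmin(pmax(tn * 51, 0), 255)
  structure(list(tn_values = as_volume(tn, vs),
                 encoded = as_volume(enc, vs),
                 cerebellum_mean_suv = ref),
            class = "tn_volume")
}

#' Decode an 8-bit encoded volume back to T/N units
#'
#' Inverse of the x51 encoding: `T/N = encoded / 51`. Voxels at exactly 255
#' were ceilinged during encoding and are flagged saturated — their true
#' T/N is only known to be >= 5.
#'
#' @param encoded volume with values in `[0, 255]`
#' @return list with `tn` (volume in T/N units) and `saturated`
#'   (logical volume)
#' @export
tn_decode <- function(encoded) {
  v <- as.numeric(encoded)
  if (any(v < 0 | v > 255)) stop("encoded values must lie in [0, 255]")
  tn <- v / 51
  sat <- v == 255
  dim(tn) <- dim(encoded); dim(sat) <- dim(encoded)
  vs <- voxel_size(encoded)
  list(tn = as_volume(tn, vs), saturated = sat)
}

#' @export
print.tn_volume <- function(x, ...) {
  cat(sprintf("<tn_volume> cerebellum mean SUV %.3f, T/N range [%.2f, %.2f]\n",
              x$cerebellum_mean_suv, min(x$tn_values), max(x$tn_values)))
  invisible(x)
}
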