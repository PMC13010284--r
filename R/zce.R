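#' Fit the per-subject T1Gd-on-T1 regression underlying the zCE map
#'
#' Ordinary least squares of normalized T1Gd on normalized T1 over
#' brain-mask voxels (a voxel-by-voxel scatter-plot fit). The fitted line is
#' the subject's no-enhancement relation between the two sequences; the
#' spread of voxels about it is summarised by the residual SD, computed with
#' the population (divide-by-n) denominator so the z-scores built from it
#' have mean 0 and SD exactly 1 over the fitted voxels.
#'
#' @param t1gd_norm,t1w_norm normalized volumes ([normalize_mri()])
#' @param brain_mask binary volume on the same grid
#' @return list with `slope`, `intercept`, `residual_sd`, `n_voxels`
#' @export
fit_t1gd_on_t1w <- function(t1gd_norm, t1w_norm, brain_mask) {
  check_same_grid(t1gd_norm, t1w_norm, "T1Gd and T1W")
  check_same_grid(t1gd_norm, brain_mask, "volumes and brain_mask")
  keep <- as.logical(brain_mask != 0)
  x <- as.numeric(t1w_norm)[keep]
  y <- as.numeric(t1gd_norm)[keep]
  if (length(x) == 0L) stop("brain_mask is empty")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("T1W is constant inside the brain mask; regression undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  residual_sd <- sqrt(mean(res^2))
  if (residual_sd == 0)
    stop("zero residual SD: T1Gd is an exact affine image of T1W, z-scores undefined")
  list(slope = slope, intercept = intercept, residual_sd = residual_sd,
       n_voxels = length(x))
}

#' z-score contrast-enhancement (zCE) map
#'
#' For every voxel of the full grid,
#' `z = (T1Gd_norm - slope * T1W_norm - intercept) / residual_sd`: the
#' voxel's distance above the subject's no-enhancement line in residual-SD
#' units. Even slight gadolinium enhancement shows as positive z. The 8-bit
#' encoding multiplies z by 51 and clips to `[0, 255]` (z of 5 or more
#' saturates; negative z — hypo-enhancement — is lost to 0).
#'
#' @inheritParams fit_t1gd_on_t1w
#' @param fit regression as returned by [fit_t1gd_on_t1w()]
#' @return a `zce_volume`: list with `z_values` and `encoded` volumes plus
#'   the fit scalars
#' @export
zce_map <- function(t1gd_norm, t1w_norm, fit) {
  check_same_grid(t1gd_norm, t1w_norm, "T1Gd and T1W")
  if (fit$residual_sd <= 0) stop("residual_sd must be positive")
  z <- (as.numeric(t1gd_norm) - fit$slope * as.numeric(t1w_norm) -
          fit$intercept) / fit$residual_sd
  dim(z) <- dim(t1gd_norm)
  vs <- voxel_size(t1gd_norm)
  enc <- pmin(pmax(z * 51, 0), 255)
  structure(list(z_values = as_volume(z, vs),
                 encoded = as_volume(enc, vs),
                 regression_slope = fit$slope,
                 regression_intercept = fit$intercept,
                 residual_sd = fit$residual_sd),
            class = "zce_volume")
}

#' @export
print.zce_volume <- function(x, ...) {
  cat(sprintf("<zce_volume> slope %.4f, intercept %.3f, residual SD %.3f\n",
              x$regression_slope, x$regression_intercept, x$residual_sd))
  invisible(x)
}
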