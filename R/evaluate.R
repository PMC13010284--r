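# coercions: accept gliomap_volume / tn_volume / bare volumes
as_tn_array <- function(x) {
  if (inherits(x, "gliomap_volume")) return(x$tn)
  if (inherits(x, "tn_volume")) return(x$tn_values)
  x
}
as_encoded_array <- function(x) {
  if (inherits(x, "gliomap_volume")) return(x$encoded)
  if (inherits(x, "tn_volume")) return(x$encoded)
  x
}

#' Voxel-wise residual error in T/N units
#'
#' Mean and SD of the absolute T/N difference between a generated map and
#' the ground-truth T/N volume over a mask, plus the signed mean
#' difference (generated minus truth), which exposes any systematic over-
#' or underestimation of uptake.
#'
#' @param gliomap generated map (`gliomap_volume`, `tn_volume` or T/N array)
#' @param truth ground truth in the same forms
#' @param mask binary evaluation mask (typically the brain mask)
#' @return list with `mean`, `sd`, `signed_mean`
#' @export
residual_error <- function(gliomap, truth, mask) {
  g <- as_tn_array(gliomap); t <- as_tn_array(truth)
  check_same_grid(g, t, "gliomap and truth")
  check_same_grid(g, mask, "volumes and mask")
  keep <- as.logical(mask != 0)
  if (!any(keep)) stop("evaluation mask is empty")
  d <- as.numeric(g)[keep] - as.numeric(t)[keep]
  list(mean = mean(abs(d)), sd = sd(abs(d)), signed_mean = mean(d))
}

gaussian_kernel2d <- function(k = 11L, sigma = 1.5) {
  r <- seq_len(k) - (k + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  kk <- outer(g, g)
  kk / sum(kk)
}

# SSIM over one slice (8-bit dynamic range), valid windows only; the
# window shrinks to the largest odd size that fits small slices
ssim_slice <- function(a, b, kern) {
  k <- nrow(kern)
  if (min(dim(a)) < k) {
    k <- min(dim(a))
    if (k %% 2 == 0) k <- k - 1L
    kern <- gaussian_kernel2d(k)
  }
  filt <- function(m) {
    conv_fwd(array(m, dim = c(dim(m), 1L)),
             matrix(as.numeric(kern), 1L), 0, k, k, 1L, 0L)[, , 1]
  }
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a^2) - mu_a^2
  vb <- filt(b^2) - mu_b^2
  vab <- filt(a * b) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
         ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}

#' Image reconstruction quality: PSNR, SNR and SSIM
#'
#' On the 8-bit encoded scale: `PSNR = 10 log10(255^2 / MSE)`;
#' `SNR = 10 log10(sum(truth^2) / sum((truth - gliomap)^2))` (reference
#' energy over error energy); SSIM with the standard constants (K1 = 0.01,
#' K2 = 0.03, dynamic range 255) and an 11x11 Gaussian window
#' (sigma = 1.5), computed per axial slice and averaged. With a mask,
#' PSNR/SNR sums run over mask voxels and SSIM over slices intersecting
#' the mask. Identical inputs give `Inf` PSNR/SNR and SSIM exactly 1.
#'
#' @param gliomap,truth encoded volumes (0-255) or objects carrying one
#' @param mask optional binary evaluation mask
#' @return list with `psnr_db`, `snr_db`, `ssim`
#' @export
image_quality <- function(gliomap, truth, mask = NULL) {
  g <- as_encoded_array(gliomap); t <- as_encoded_array(truth)
  check_same_grid(g, t, "gliomap and truth")
  gv <- as.numeric(g); tv <- as.numeric(t)
  if (any(gv < 0 | gv > 255 | tv < 0 | tv > 255))
    stop("encoded values must lie in [0, 255]")
  keep <- if (is.null(mask)) rep(TRUE, length(gv)) else as.logical(mask != 0)
  err2 <- sum((tv[keep] - gv[keep])^2)
  mse <- err2 / sum(keep)
  psnr <- if (mse == 0) Inf else 10 * log10(255^2 / mse)
  snr <- if (err2 == 0) Inf else 10 * log10(sum(tv[keep]^2) / err2)
  kern <- gaussian_kernel2d()
  nk <- dim(g)[3]
  use <- if (is.null(mask)) seq_len(nk)
         else which(vapply(seq_len(nk), function(k) any(mask[, , k] != 0),
                           logical(1)))
  sv <- vapply(use, function(k) ssim_slice(bare(g)[, , k], bare(t)[, , k],
                                           kern), numeric(1))
  list(psnr_db = psnr, snr_db = snr, ssim = mean(sv))
}

#' Sørensen-Dice overlap between thresholded lesions
#'
#' For each T/N threshold `t`, the predicted lesion is the voxel set with
#' `gliomap T/N >= t` and likewise for the truth;
#' `Dice = 2|A ∩ B| / (|A| + |B|)`. Both sets empty gives 1 (perfect
#' agreement on absence); exactly one empty gives 0.
#'
#' @param gliomap,truth T/N volumes (or objects carrying one)
#' @param thresholds positive T/N thresholds
#' @return tibble with columns `threshold`, `dice`
#' @export
dice_vs_threshold <- function(gliomap, truth, thresholds = seq(1.1, 2, 0.1)) {
  g <- as.numeric(as_tn_array(gliomap)); t <- as.numeric(as_tn_array(truth))
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  dice <- vapply(thresholds, function(th) {
    a <- g >= th; b <- t >= th
    na <- sum(a); nb <- sum(b)
    if (na + nb == 0L) return(1)
    2 * sum(a & b) / (na + nb)
  }, numeric(1))
  tibble::tibble(threshold = thresholds, dice = dice)
}

#' Lesion volume-expansion ratio over the enhancing lesion
#'
#' How much a T/N-thresholded lesion expands the treated volume beyond the
#' gadolinium-enhancing lesion:
#' `|enhancing ∪ lesion| / |enhancing|` (always >= 1). With
#' `union = FALSE` the plain ratio `|lesion| / |enhancing|` is returned
#' instead.
#'
#' @param lesion binary/logical lesion volume (e.g. `tn >= 1.5`)
#' @param enhancing_mask binary gadolinium-enhancing lesion mask
#' @param union use the union construction (default) or the plain ratio
#' @return a single ratio
#' @export
volume_expansion <- function(lesion, enhancing_mask, union = TRUE) {
  e <- as.logical(enhancing_mask != 0)
  l <- as.logical(lesion != 0)
  if (!any(e)) stop("enhancing mask is empty")
  if (union) sum(e | l) / sum(e) else sum(l) / sum(e)
}

#' Statistics of a cubic voxel-of-interest
#'
#' Mean and SD of the decoded T/N values over the cubic VOI (default edge
#' 10 mm, i.e. 1 cm^3) centered at a physical coordinate — the quantity
#' compared against cell counts from image-guided tissue sampling.
#'
#' @param gliomap T/N volume (or object carrying one) with voxel size
#' @param position_mm physical coordinate (length 3, mm) of the VOI center
#' @param voi_edge_mm cube edge length in mm (default 10)
#' @return list with `mean_tn`, `sd_tn`, `n_voxels`
#' @export
voi_statistics <- function(gliomap, position_mm, voi_edge_mm = 10) {
  vol <- as_tn_array(gliomap)
  vs <- voxel_size(vol)
  n <- dim(vol)
  half <- voi_edge_mm / 2
  lo <- position_mm - half; hi <- position_mm + half
  if (any(lo < 0) || any(hi > n * vs))
    stop("VOI extends outside the volume")
  # half-open [lo, hi): an aligned 10 mm cube on a 2 mm grid is 5^3 voxels
  idx <- lapply(1:3, function(d) {
    centers <- (seq_len(n[d]) - 0.5) * vs[d]
    which(centers >= lo[d] & centers < hi[d])
  })
  vals <- bare(vol)[idx[[1]], idx[[2]], idx[[3]]]
  list(mean_tn = mean(vals), sd_tn = sd(as.numeric(vals)),
       n_voxels = length(vals))
}

#' Linear regression of VOI signal on tumor cell density
#'
#' Ordinary least squares of the VOI-mean T/N value on cell density
#' (cells/mm2), with the two-sided t-test p-value for the slope and the
#' Pearson correlation — the histological-validation analysis relating
#' the generated map to tissue-sampling cell counts.
#'
#' @param samples data frame with columns `voi_mean_tn` and `cell_density`
#' @return a `density_regression`: list with `slope`, `intercept`,
#'   `p_value`, `r`, standard errors, `n`, and the underlying `lm` fit
#' @export
density_regression <- function(samples) {
  if (nrow(samples) < 3) stop("need at least 3 samples")
  if (sd(samples$cell_density) == 0)
    stop("cell density is constant; regression undefined")
  fit <- lm(voi_mean_tn ~ cell_density, data = samples)
  # summary.lm warns on an exactly collinear (zero-residual) fit; that is a
  # legitimate input here (noise-free validation lines)
  sm <- suppressWarnings(summary(fit))$coefficients
  out <- list(slope = sm["cell_density", "Estimate"],
              intercept = sm["(Intercept)", "Estimate"],
              p_value = sm["cell_density", "Pr(>|t|)"],
              r = cor(samples$cell_density, samples$voi_mean_tn),
              se_slope = sm["cell_density", "Std. Error"],
              se_intercept = sm["(Intercept)", "Std. Error"],
              n = nrow(samples), fit = fit)
  class(out) <- "density_regression"
  out
}

#' @export
print.density_regression <- function(x, ...) {
  cat(sprintf("<density_regression> T/N = %.3g x density + %.3g (r = %.2f, P = %.3g, n = %d)\n",
              x$slope, x$intercept, x$r, x$p_value, x$n))
  invisible(x)
}

#' Full per-subject evaluation report
#'
#' Runs the whole quality battery of a generated map against the
#' ground-truth T/N volume: residual T/N error, PSNR/SNR/SSIM,
#' Dice-versus-threshold curve, and volume-expansion curves for both the
#' generated map and the truth relative to the enhancing lesion.
#'
#' @param gliomap a `gliomap_volume` (or T/N + encoded volumes)
#' @param truth a `tn_volume` (or T/N volume)
#' @param brain_mask,enhancing_mask binary masks
#' @param thresholds T/N thresholds for the curves
#' @return an `evaluation_report`: list with `subject_id`, `residual`,
#'   `quality`, `dice_curve`, `expansion_curve`
#' @export
evaluate_subject <- function(gliomap, truth, brain_mask, enhancing_mask,
                             thresholds = seq(1.1, 2, 0.1)) {
  g_tn <- as_tn_array(gliomap); t_tn <- as_tn_array(truth)
  exp_rows <- lapply(thresholds, function(th) {
    tibble::tibble(threshold = th,
                   expansion_gliomap = volume_expansion(g_tn >= th,
                                                        enhancing_mask),
                   expansion_truth = volume_expansion(t_tn >= th,
                                                      enhancing_mask))
  })
  out <- list(subject_id = if (inherits(gliomap, "gliomap_volume"))
                gliomap$subject_id else NA_character_,
              residual = residual_error(gliomap, truth, brain_mask),
              quality = image_quality(gliomap, truth, brain_mask),
              dice_curve = dice_vs_threshold(gliomap, truth, thresholds),
              expansion_curve = do.call(rbind, exp_rows))
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  d15 <- x$dice_curve$dice[which.min(abs(x$dice_curve$threshold - 1.5))]
  cat(sprintf(paste0("<evaluation_report> %s: residual %.3f ± %.3f T/N, ",
                     "PSNR %.1f dB, SSIM %.3f, Dice@~1.5 %.3f\n"),
              x$subject_id, x$residual$mean, x$residual$sd,
              x$quality$psnr_db, x$quality$ssim, d15))
  invisible(x)
}
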