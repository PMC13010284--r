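tnv <- function(values, dims = c(length(values), 1, 1), vs = c(1, 1, 1)) {
  as_volume(array(values, dim = dims), vs)
}

test_that("residual error matches arithmetic and folded-normal oracles", {
  s <- quiet_subject()
  tn <- tn_normalize(s$pet_suv, s$cerebellum_mask)
  r0 <- residual_error(tn$tn_values, tn$tn_values, s$brain_mask)
  expect_equal(r0, list(mean = 0, sd = 0, signed_mean = 0))
  # constant encoded offset of 5.1 is 0.1 in T/N units
  off <- as_volume(bare(tn$encoded) + 5.1, voxel_size(tn$encoded))
  r1 <- residual_error(tn_decode(pmin(off, 255))$tn, tn$tn_values,
                       s$brain_mask)
  expect_equal(r1$mean, 0.1, tolerance = 1e-6)
  expect_equal(r1$signed_mean, 0.1, tolerance = 1e-6)
  # |N(0, 0.05)| has mean 0.05*sqrt(2/pi)
  set.seed(12)
  n <- 60^3
  noise <- rnorm(n, 0, 0.05)
  truth <- tnv(rep(1.5, n), dims = c(60, 60, 60))
  noisy <- tnv(1.5 + noise, dims = c(60, 60, 60))
  r2 <- residual_error(noisy, truth, tnv(rep(1, n), dims = c(60, 60, 60)))
  expect_equal(r2$mean, 0.05 * sqrt(2 / pi), tolerance = 0.01)
  expect_error(residual_error(truth, truth, tnv(rep(0, n),
                                                dims = c(60, 60, 60))),
               "empty")
})

test_that("PSNR and SNR match their closed forms", {
  a <- tnv(rep(100, 1000), dims = c(10, 10, 10))
  b <- tnv(rep(110, 1000), dims = c(10, 10, 10))
  q <- image_quality(b, a)
  expect_equal(q$psnr_db, 10 * log10(255^2 / 100), tolerance = 1e-12)
  expect_equal(q$snr_db, 10 * log10(sum(rep(100, 1000)^2) / (1000 * 100)),
               tolerance = 1e-12)
  expect_equal(image_quality(a, a)$psnr_db, Inf)
  expect_equal(image_quality(a, a)$ssim, 1)
  # PSNR strictly decreases as MSE grows
  set.seed(3)
  base <- array(runif(1000, 0, 200), dim = c(10, 10, 10))
  psnrs <- vapply(c(1, 5, 20), function(s)
    image_quality(tnv(pmin(pmax(base + s, 0), 255), dims = c(10, 10, 10)),
                  tnv(base, dims = c(10, 10, 10)))$psnr_db, numeric(1))
  expect_true(all(diff(psnrs) < 0))
  expect_error(image_quality(tnv(rep(300, 8), dims = c(2, 2, 2)),
                             tnv(rep(0, 8), dims = c(2, 2, 2))), "255")
})

test_that("SSIM is symmetric, maximal iff identical, low for inverted structure", {
  set.seed(14)
  sl <- matrix(runif(24 * 24, 0, 255), 24, 24)
  # smooth it a little so there is local structure
  sl <- (sl + sl[c(2:24, 24), ] + sl[, c(2:24, 24)]) / 3
  a <- as_volume(array(sl, dim = c(24, 24, 1)))
  b <- as_volume(array(255 - sl, dim = c(24, 24, 1)))
  qa <- image_quality(a, b)
  qb <- image_quality(b, a)
  expect_equal(qa$ssim, qb$ssim, tolerance = 1e-12)
  expect_lt(qa$ssim, 0.2)
  expect_equal(image_quality(a, a)$ssim, 1)
  expect_lt(image_quality(as_volume(array(sl * 0.7, dim = c(24, 24, 1))),
                          a)$ssim, 1)
})

test_that("Dice agrees exactly with a brute-force set oracle", {
  set.seed(15)
  dims <- c(10, 10, 10)
  g <- tnv(runif(1000, 0, 3), dims = dims)
  t <- tnv(runif(1000, 0, 3), dims = dims)
  ths <- c(0.5, 1, 1.5, 2, 2.9)
  curve <- dice_vs_threshold(g, t, ths)
  for (i in seq_along(ths)) {
    A <- which(as.numeric(g) >= ths[i])
    B <- which(as.numeric(t) >= ths[i])
    oracle <- if (length(A) + length(B) == 0) 1 else
      2 * length(intersect(A, B)) / (length(A) + length(B))
    expect_identical(curve$dice[i], oracle)
  }
  # counting example: |A| = 4, |B| = 6, overlap 3
  a <- tnv(c(rep(2, 3), rep(2, 1), rep(0, 3), rep(0, 3)), dims = c(10, 1, 1))
  b <- tnv(c(rep(2, 3), rep(0, 1), rep(2, 3), rep(0, 3)), dims = c(10, 1, 1))
  expect_equal(dice_vs_threshold(a, b, 1)$dice, 0.6)
  expect_equal(dice_vs_threshold(g, g, ths)$dice, rep(1, 5))
  expect_equal(dice_vs_threshold(g, t, 99)$dice, 1)     # both empty
  expect_equal(dice_vs_threshold(g, tnv(rep(0, 1000), dims = dims),
                                 2.9)$dice, 0)          # one empty
  expect_error(dice_vs_threshold(g, t, c(1, -2)), "positive")
})

test_that("volume expansion follows the union counting oracle", {
  enh <- tnv(c(rep(1, 100), rep(0, 100)), dims = c(200, 1, 1))
  lesion <- tnv(c(rep(1, 50), rep(0, 50), rep(1, 29), rep(0, 71)),
                dims = c(200, 1, 1))
  expect_equal(volume_expansion(lesion, enh), 1.29)
  expect_equal(volume_expansion(lesion, enh, union = FALSE), 0.79)
  inside <- tnv(c(rep(1, 40), rep(0, 160)), dims = c(200, 1, 1))
  expect_equal(volume_expansion(inside, enh), 1)
  expect_equal(volume_expansion(tnv(rep(0, 200), dims = c(200, 1, 1)), enh), 1)
  expect_error(volume_expansion(lesion, tnv(rep(0, 200),
                                            dims = c(200, 1, 1))), "empty")
  # union construction is never below 1
  set.seed(16)
  for (i in 1:5) {
    l <- tnv(rbinom(200, 1, 0.3), dims = c(200, 1, 1))
    expect_gte(volume_expansion(l, enh), 1)
  }
})

test_that("VOI statistics are exact on constructed cubes", {
  dims <- c(20, 20, 20)
  uni <- tnv(rep(1.5, 8000), dims = dims, vs = c(2, 2, 2))
  v <- voi_statistics(uni, c(20, 20, 20), 10)
  expect_equal(v$mean_tn, 1.5)
  expect_equal(v$sd_tn, 0)
  expect_equal(v$n_voxels, 125L)
  # half-half cube: values 1 for x-index <= 10, 2 above
  arr <- array(1, dim = dims); arr[11:20, , ] <- 2
  hh <- as_volume(arr, c(2, 2, 2))
  # VOI centered on the boundary plane x = 20 mm
  v2 <- voi_statistics(hh, c(20, 20, 20), 8)
  expect_equal(v2$mean_tn, 1.5)
  expect_error(voi_statistics(uni, c(2, 2, 2), 10), "outside")
  expect_error(voi_statistics(uni, c(39, 20, 20), 10), "outside")
})

test_that("density regression recovers a known line and matches lm", {
  d <- seq(0, 30000, length.out = 16)
  exact <- tibble::tibble(cell_density = d,
                          voi_mean_tn = 5.8e-5 * d + 1.0)
  fit <- density_regression(exact)
  expect_equal(fit$slope, 5.8e-5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  # three points, two sharing a density, on an exact line
  tri <- tibble::tibble(cell_density = c(1000, 1000, 5000),
                        voi_mean_tn = 1 + 2e-4 * c(1000, 1000, 5000))
  ft <- density_regression(tri)
  expect_equal(ft$slope, 2e-4, tolerance = 1e-12)
  expect_error(density_regression(exact[1:2, ]), "3 samples")
  expect_error(density_regression(tibble::tibble(cell_density = rep(1, 5),
                                                 voi_mean_tn = 1:5)),
               "constant")
  # noisy recovery: slope within 2 SE, significantly positive
  set.seed(17)
  noisy <- tibble::tibble(cell_density = runif(16, 0, 30000))
  noisy$voi_mean_tn <- 1 + 5.8e-5 * noisy$cell_density + rnorm(16, 0, 0.3)
  fn <- density_regression(noisy)
  expect_lt(abs(fn$slope - 5.8e-5), 2 * fn$se_slope)
  expect_lt(fn$p_value, 0.05)
  expect_gt(fn$slope, 0)
  td <- tidy(fn)
  expect_equal(td$estimate[td$term == "cell_density"], fn$slope)
  expect_equal(glance(fn)$nobs, 16)
})

test_that("a perfect map reproduces the degenerate report fixed points", {
  s <- quiet_subject()
  p <- preprocess_subject(s)
  fake <- list(encoded = p$tn$encoded, tn = p$tn$tn_values,
               subject_id = s$subject_id, failed_slices = integer(0))
  class(fake) <- "gliomap_volume"
  rep <- evaluate_subject(fake, p$tn, s$brain_mask, s$enhancing_mask)
  expect_equal(rep$residual$mean, 0)
  expect_true(all(rep$dice_curve$dice == 1))
  expect_equal(rep$quality$ssim, 1)
  expect_equal(rep$expansion_curve$expansion_gliomap,
               rep$expansion_curve$expansion_truth)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$residual_mean, 0)
})
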