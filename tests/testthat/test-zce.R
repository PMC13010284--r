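vol3 <- function(values, dims = c(length(values), 1, 1)) {
  as_volume(array(values, dim = dims))
}

test_that("the voxel-wise fit matches the closed-form OLS oracle", {
  # construction: each T1W value appears twice with residuals +s and -s,
  # so the true line y = x has balanced residuals of magnitude exactly s
  x <- rep(seq(10, 90, by = 10), each = 2)
  s <- 4
  y <- x + rep(c(s, -s), times = 9)
  fit <- fit_t1gd_on_t1w(vol3(y), vol3(x), vol3(rep(1, 18)))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$residual_sd, s, tolerance = 1e-12)

  # independent oracle: lm() on a random scatter
  set.seed(21)
  x2 <- runif(400, 0, 200)
  y2 <- 1.7 * x2 + 12 + rnorm(400, 0, 6)
  fit2 <- fit_t1gd_on_t1w(vol3(y2), vol3(x2), vol3(rep(1, 400)))
  ref <- lm(y2 ~ x2)
  expect_equal(fit2$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit2$residual_sd,
               sqrt(mean(residuals(ref)^2)), tolerance = 1e-10)
})

test_that("degenerate fits raise the documented errors", {
  x <- vol3(seq(1, 10))
  y_exact <- vol3(2 * seq(1, 10) + 10)
  m <- vol3(rep(1, 10))
  expect_error(fit_t1gd_on_t1w(y_exact, x, m), "zero residual")
  expect_error(fit_t1gd_on_t1w(y_exact, vol3(rep(5, 10)), m), "constant")
  expect_error(fit_t1gd_on_t1w(y_exact, x, vol3(rep(0, 10))), "empty")
  expect_error(zce_map(y_exact, x, list(slope = 2, intercept = 10,
                                        residual_sd = 0)), "positive")
})

test_that("z-scores are standardized over the fitted voxels", {
  s <- quiet_subject()
  p <- preprocess_subject(s)
  z <- p$zce$z_values[s$brain_mask == 1]
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-6)
})

test_that("the 8-bit zCE encoding is the clipped 51-fold z-score", {
  fit <- list(slope = 1, intercept = 0, residual_sd = 2)
  t1w <- vol3(c(10, 10, 10, 10))
  t1gd <- vol3(c(10, 14, 30, 8))   # z = 0, 2, 10, -1
  z <- zce_map(t1gd, t1w, fit)
  expect_equal(as.numeric(z$z_values), c(0, 2, 10, -1))
  expect_equal(as.numeric(z$encoded), c(0, 102, 255, 0))
  # monotone in z with saturation at z = 5
  zs <- seq(-2, 8, by = 0.25)
  enc <- as.numeric(zce_map(vol3(zs * 2), vol3(rep(0, length(zs))),
                            fit)$encoded)
  expect_true(all(diff(enc) >= 0))
  expect_true(all(enc[zs >= 5] == 255))
})

test_that("enhancing tissue carries higher encoded zCE than the rest of the brain", {
  cohort <- generate_cohort(small_spec(noise_sd = c(t1w = 1, t2w = 1,
                                                    t1gd = 1, pet = 0.02)),
                            3, seed = 31)
  for (s in cohort) {
    p <- preprocess_subject(s)
    inside <- mean(p$zce$encoded[s$enhancing_mask == 1])
    outside <- mean(p$zce$encoded[s$brain_mask == 1 & s$enhancing_mask == 0])
    expect_gt(inside, outside)
  }
})

test_that("the fit recovers the generative no-enhancement relation", {
  # noiseless T1W, noisy T1Gd, no enhancement: the generative relation is
  # t1gd_norm = (m1/m3) * t1w_norm with residual SD 75*sigma/m3
  spec <- small_spec(noise_sd = c(t1w = 0, t2w = 0, t1gd = 2, pet = 0),
                     density_params = list(peak_density = 30000,
                                           suv_per_cell = 8.7e-5,
                                           t2_density_gain = 40,
                                           enhancement_gain = 0),
                     seed = 41L)
  s <- generate_subject(spec, 1)
  t1w_n <- normalize_mri(s$t1w, s$brain_mask)
  t1gd_n <- normalize_mri(s$t1gd, s$brain_mask)
  fit <- fit_t1gd_on_t1w(t1gd_n, t1w_n, s$brain_mask)
  m1 <- attr(t1w_n, "mode_value"); m3 <- attr(t1gd_n, "mode_value")
  true_slope <- (75 / m3) * s$gains[["t1gd"]] / ((75 / m1) * s$gains[["t1w"]])
  n <- fit$n_voxels
  x <- as.numeric(t1w_n)[s$brain_mask == 1]
  se_slope <- fit$residual_sd / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(fit$slope - true_slope), 2 * se_slope + 1e-6)
})
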