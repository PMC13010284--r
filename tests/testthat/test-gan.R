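# tiny synthetic task: target = mean of the source channels (affine map).
# Sources are smooth random fields: a strided encoder-decoder cannot
# represent pixel-level white noise, and real slices are smooth.
affine_pairs <- function(n, size = 32L, seed = 1) {
  set.seed(seed)
  g <- seq_len(size) / size
  lapply(seq_len(n), function(i) {
    f <- runif(4, 0.5, 2)
    base <- 127.5 * (1 + outer(sin(2 * pi * (f[1] * g + f[2])),
                               cos(2 * pi * (f[3] * g + f[4]))))
    src <- array(0, dim = c(size, size, 3))
    src[, , 1] <- base
    src[, , 2] <- pmin(1.2 * base, 255)
    src[, , 3] <- 0.5 * base
    src <- round(src)
    p <- list(subject_id = sprintf("aff-%02d", i), slice_index = i,
              source = src, target = round((src[, , 1] + src[, , 2] +
                                              src[, , 3]) / 3),
              mirrored = FALSE)
    class(p) <- "source_target_pair"
    p
  })
}

tiny_config <- function(...) {
  gan_config(image_size = 32L, generator_base_channels = 8L,
             discriminator_base_channels = 8L, ...)
}

test_that("config validation enforces the documented bounds", {
  expect_error(gan_config(epochs = 0), "epochs")
  expect_error(gan_config(lambda_l1 = -1), "lambda_l1")
  expect_error(gan_config(image_size = 48), "power of two")
  expect_error(gan_config(image_size = 16), "power of two")
  expect_error(gan_config(device = "gpu"), "cpu")
  desk <- gan_preset("desk")
  expect_equal(desk$image_size, 64L)
  expect_equal(desk$lambda_l1, 100)
  full <- gan_preset("full")
  expect_equal(full$epochs, 200L)
  expect_equal(full$generator_base_channels, 64L)
})

test_that("training is deterministic under a fixed seed and config", {
  pairs <- affine_pairs(6)
  cfg <- tiny_config(epochs = 1L, seed = 5L)
  m1 <- gan_train(pairs, cfg)
  m2 <- gan_train(pairs, cfg)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$G, m2$G)
})

test_that("the translator learns a deterministic affine task", {
  pairs <- affine_pairs(40)
  val <- affine_pairs(6, seed = 99)
  m <- gan_train(pairs, tiny_config(epochs = 10L, seed = 2L), val)
  tr <- m$trace
  expect_true(all(is.finite(tr$loss_d)))
  expect_true(all(is.finite(tr$loss_g_adv)))
  expect_true(all(is.finite(tr$loss_l1)))
  # learnability: held-out residual at least halves from the first epoch
  expect_lt(tr$val_residual_tn[nrow(tr)], tr$val_residual_tn[1] / 2)
  # stability: no epoch diverges past 10x the first epoch's losses
  expect_true(all(tr$loss_d <= 10 * tr$loss_d[1]))
  expect_true(all(tr$loss_l1 <= 10 * tr$loss_l1[1]))
})

test_that("training rejects empty or mismatched inputs", {
  expect_error(gan_train(list(), tiny_config()), "empty")
  expect_error(gan_train(affine_pairs(2, size = 32), gan_config()), "64")
})

test_that("a lambda-free run still trains on the adversarial term alone", {
  m <- gan_train(affine_pairs(4), tiny_config(epochs = 1L, lambda_l1 = 0))
  expect_true(all(is.finite(m$trace$loss_g_adv)))
  expect_equal(m$config$lambda_l1, 0)
})

test_that("map generation is bounded, deterministic and flags empty slices", {
  s <- quiet_subject()
  p <- preprocess_subject(s)
  m <- gan_train(affine_pairs(4, size = 64), gan_preset("desk", epochs = 1L,
                                                        seed = 3L))
  gm1 <- generate_gliomap(m, p)
  gm2 <- generate_gliomap(m, p)
  expect_identical(gm1$encoded, gm2$encoded)
  expect_true(all(is.finite(gm1$encoded)))
  expect_true(all(gm1$encoded >= 0 & gm1$encoded <= 255))
  expect_equal(as.numeric(gm1$tn), as.numeric(gm1$encoded) / 51)
  # slices without brain coverage are flagged low-content, not failed
  empty <- which(apply(bare(s$brain_mask), 3, function(m) mean(m != 0)) < 0.05)
  expect_setequal(gm1$low_content_slices, empty)
})

test_that("a collapsed generator's flat output is flagged as failed", {
  s <- quiet_subject()
  p <- preprocess_subject(s)
  set.seed(8)
  G <- gliomapr:::make_generator(64L, 8L)
  # zeroed weights collapse every slice to a constant mid-gray field —
  # the reconstruction-failure mode the dynamic-range floor must catch
  G$enc <- gliomapr:::tree_zero(G$enc)
  G$dec <- gliomapr:::tree_zero(G$dec)
  gm <- generate_gliomap(list(G = G, config = gan_preset("desk")), p)
  brainy <- which(apply(gliomapr:::bare(s$brain_mask), 3,
                        function(m) mean(m != 0)) >= 0.05)
  expect_setequal(gm$failed_slices, brainy)
})
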