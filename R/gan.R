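#' Configuration of the conditional image translator
#'
#' Hyperparameters follow the published pix2pix defaults: adversarial +
#' L1 objective with `lambda_l1 = 100`, Adam at learning rate 2e-4 with
#' `beta1 = 0.5`, 4x4 convolutions, a U-Net generator and a 70x70
#' receptive-field PatchGAN discriminator. Two presets are provided:
#' `"desk"` (64 px, 16 base channels, 10 epochs) trains in minutes on one
#' CPU; `"full"` (256 px, 64 base channels, 200 epochs) is the
#' full-scale configuration.
#'
#' @param image_size square slice size in pixels, a power of two >= 32
#' @param generator_base_channels,discriminator_base_channels channel width
#'   of the first conv layer (doubling per downsampling, capped at 8x)
#' @param lambda_l1 weight of the L1 reconstruction term (>= 0)
#' @param epochs training epochs (>= 1)
#' @param batch_size pairs per optimizer step
#' @param learning_rate,beta1 Adam parameters
#' @param seed seed for weight initialisation and shuffling
#' @param dropout apply 0.5 dropout to the three innermost decoder blocks
#'   during training (the published full-scale default); disabled in the
#'   desk preset, where the small slice set makes the extra stochasticity
#'   counterproductive
#' @param device compute device label (only "cpu" is available)
#' @param checkpoint_dir optional directory for per-interval weight dumps
#' @param checkpoint_interval epochs between checkpoints
#' @param range_floor dynamic-range floor (8-bit units) under which a
#'   generated slice with brain content is flagged as failed
#' @return a `gan_config` list
#' @export
gan_config <- function(image_size = 64L,
                       generator_base_channels = 16L,
                       discriminator_base_channels = 16L,
                       lambda_l1 = 100,
                       epochs = 10L,
                       batch_size = 1L,
                       learning_rate = 2e-4,
                       beta1 = 0.5,
                       dropout = FALSE,
                       seed = 1L,
                       device = "cpu",
                       checkpoint_dir = NULL,
                       checkpoint_interval = 5L,
                       range_floor = 5) {
  cfg <- list(image_size = as.integer(image_size),
              generator_base_channels = as.integer(generator_base_channels),
              discriminator_base_channels = as.integer(discriminator_base_channels),
              lambda_l1 = lambda_l1, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, beta1 = beta1,
              dropout = isTRUE(dropout),
              seed = as.integer(seed), device = device,
              checkpoint_dir = checkpoint_dir,
              checkpoint_interval = as.integer(checkpoint_interval),
              range_floor = range_floor)
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  if (cfg$lambda_l1 < 0) stop("lambda_l1 must be >= 0")
  p <- log2(cfg$image_size)
  if (cfg$image_size < 32 || p != round(p))
    stop("image_size must be a power of two >= 32")
  if (!identical(device, "cpu")) stop("only device = 'cpu' is available")
  class(cfg) <- "gan_config"
  cfg
}

#' @rdname gan_config
#' @param preset "desk" or "full"
#' @param ... overrides passed to [gan_config()]
#' @export
gan_preset <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    desk = list(image_size = 64L, generator_base_channels = 16L,
                discriminator_base_channels = 16L, epochs = 10L),
    full = list(image_size = 256L, generator_base_channels = 64L,
                 discriminator_base_channels = 64L, epochs = 200L,
                 dropout = TRUE))
  do.call(gan_config, utils::modifyList(base, list(...)))
}

pair_to_xy <- function(pair) {
  s <- dim(pair$target)
  list(x = pair$source / 255,
       y = array(pair$target / 255, dim = c(s[1], s[2], 1L)))
}

# mean absolute generator error on pairs, in T/N units (255/51 = 5)
validation_residual <- function(G, pairs) {
  if (length(pairs) == 0L) return(NA_real_)
  mean(vapply(pairs, function(p) {
    xy <- pair_to_xy(p)
    mean(abs(gen_forward(G, xy$x)$out - xy$y)) * 5
  }, numeric(1)))
}

#' Train the conditional adversarial image translator
#'
#' Alternating updates of the PatchGAN discriminator (real vs generated
#' target, conditioned on the source) and the U-Net generator
#' (adversarial term plus `lambda_l1` times the L1 distance to the real
#' target). The whole run — weight initialisation, shuffling — is a
#' deterministic function of `config$seed`.
#'
#' @param pairs training `source_target_pair` list (see [build_pairs()])
#' @param config a [gan_config()]
#' @param val_pairs optional held-out pairs; their mean absolute error in
#'   T/N units is recorded per epoch in the trace
#' @return a `gan_model`: list with `G` (generator weights), `D`, `config`
#'   and `trace` (tibble: epoch, loss_d, loss_g_adv, loss_l1,
#'   val_residual_tn)
#' @export
gan_train <- function(pairs, config = gan_config(), val_pairs = NULL) {
  if (length(pairs) == 0L) stop("training set is empty")
  s <- dim(pairs[[1]]$target)[1]
  if (s != config$image_size)
    stop(sprintf("pairs are %d px but config$image_size is %d", s,
                 config$image_size))
  set.seed(config$seed)
  G <- make_generator(config$image_size, config$generator_base_channels)
  D <- make_discriminator(config$discriminator_base_channels)
  pg <- list(enc = G$enc, dec = G$dec)
  pd <- list(layers = D$layers)
  stG <- adam_init(pg)
  stD <- adam_init(pd)
  n <- length(pairs)
  bs <- max(1L, config$batch_size)
  lam <- config$lambda_l1
  trace <- vector("list", config$epochs)

  n_const <- ceiling(config$epochs / 2)  # then linear decay to zero
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate *
      min(1, (config$epochs - epoch + 1) / (config$epochs - n_const + 1))
    ord <- sample.int(n)
    ep <- c(loss_d = 0, loss_g_adv = 0, loss_l1 = 0)
    nb <- 0L
    for (start in seq(1, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      caches <- vector("list", length(idx))
      gD <- NULL
      ld <- 0
      for (j in seq_along(idx)) {
        xy <- pair_to_xy(pairs[[idx[j]]])
        fw <- gen_forward(G, xy$x, train = config$dropout)
        caches[[j]] <- list(xy = xy, fw = fw)
        r <- disc_forward(D, concat_ch(xy$x, xy$y))
        f <- disc_forward(D, concat_ch(xy$x, fw$out))
        ld <- ld + 0.5 * (bce_logits(r$out, 1) + bce_logits(f$out, 0))
        br <- disc_backward(D, r, 0.5 * bce_logits_grad(r$out, 1))
        bf <- disc_backward(D, f, 0.5 * bce_logits_grad(f$out, 0))
        g <- tree_add(br$grads, bf$grads)
        gD <- if (is.null(gD)) g else tree_add(gD, g)
      }
      gD <- tree_scale(gD, 1 / length(idx))
      resD <- adam_step(pd, gD, stD, lr, config$beta1)
      pd <- resD$params; stD <- resD$state; D$layers <- pd$layers

      gG <- NULL
      ladv <- 0; ll1 <- 0
      for (j in seq_along(idx)) {
        xy <- caches[[j]]$xy; fw <- caches[[j]]$fw
        f2 <- disc_forward(D, concat_ch(xy$x, fw$out))
        ladv <- ladv + bce_logits(f2$out, 1)
        ll1 <- ll1 + mean(abs(fw$out - xy$y))
        b2 <- disc_backward(D, f2, bce_logits_grad(f2$out, 1))
        nch <- dim(xy$x)[3]
        dfake <- b2$dx[, , nch + 1L, drop = FALSE]
        if (lam > 0)
          dfake <- dfake + lam * sign(fw$out - xy$y) / length(xy$y)
        g <- gen_backward(G, fw, dfake)
        gG <- if (is.null(gG)) g else tree_add(gG, g)
      }
      gG <- tree_scale(gG, 1 / length(idx))
      resG <- adam_step(pg, gG, stG, lr, config$beta1)
      pg <- resG$params; stG <- resG$state
      G$enc <- pg$enc; G$dec <- pg$dec

      ep <- ep + c(ld / length(idx), ladv / length(idx), ll1 / length(idx))
      nb <- nb + 1L
      if (!all(is.finite(ep)))
        stop(sprintf("non-finite loss in epoch %d (d=%.3g, g_adv=%.3g, l1=%.3g)",
                     epoch, ep[1], ep[2], ep[3]))
    }
    ep <- ep / nb
    vres <- validation_residual(G, val_pairs)
    trace[[epoch]] <- tibble::tibble(epoch = epoch, loss_d = ep[["loss_d"]],
                                     loss_g_adv = ep[["loss_g_adv"]],
                                     loss_l1 = ep[["loss_l1"]],
                                     val_residual_tn = vres)
    if (!is.null(config$checkpoint_dir) &&
        (epoch %% config$checkpoint_interval == 0L ||
         epoch == config$epochs)) {
      dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(list(G = G, config = config, epoch = epoch),
              file.path(config$checkpoint_dir,
                        sprintf("weights_epoch%03d.rds", epoch)))
    }
  }
  model <- list(G = G, D = D, config = config,
                trace = do.call(rbind, trace))
  class(model) <- "gan_model"
  model
}

#' @export
print.gan_model <- function(x, ...) {
  tr <- x$trace[nrow(x$trace), ]
  cat(sprintf(paste0("<gan_model> %d px, %d epochs; final losses: D %.3f, ",
                     "G adv %.3f, L1 %.4f, val residual %.3f T/N\n"),
              x$config$image_size, x$config$epochs, tr$loss_d, tr$loss_g_adv,
              tr$loss_l1, tr$val_residual_tn))
  invisible(x)
}

# place a generated square slice back onto the original in-plane grid
unfit_square <- function(sq, n) {
  s <- nrow(sq)
  out <- matrix(0, n[1], n[2])
  src <- dst <- list()
  for (d in 1:2) {
    if (n[d] >= s) {
      o <- floor((n[d] - s) / 2)
      dst[[d]] <- (o + 1):(o + s); src[[d]] <- 1:s
    } else {
      o <- floor((s - n[d]) / 2)
      dst[[d]] <- 1:n[d]; src[[d]] <- (o + 1):(o + n[d])
    }
  }
  out[dst[[1]], dst[[2]]] <- sq[src[[1]], src[[2]]]
  out
}

#' Generate a PET-like T/N map ("gliomap") for one subject
#'
#' Runs the trained generator on every axial slice of a preprocessed
#' subject (sources built exactly as during training) and re-stacks the
#' outputs into a volume on the subject grid; in-plane regions outside the
#' model's field of view are zero. The volume decodes to T/N units as
#' `encoded / 51`. Slices whose generated dynamic range collapses below
#' `config$range_floor` despite brain content are flagged failed;
#' brain-free slices are flagged low-content.
#'
#' @param model a `gan_model` from [gan_train()] (or a list with `G` and
#'   `config`)
#' @param processed a `processed_subject` ([preprocess_subject()])
#' @param slice_axis slicing axis used at training time (default 3)
#' @param min_brain_fraction brain coverage below which a slice is
#'   considered low-content (default 0.05)
#' @param mask_to_brain zero the generated map outside the brain mask
#'   (default TRUE): a tumor-to-normal ratio is only defined over brain
#'   tissue, and conv-border artifacts in air would otherwise masquerade
#'   as lesions
#' @return a `gliomap_volume`: list with `encoded` (0-255 volume), `tn`
#'   (T/N volume), `subject_id`, `failed_slices`, `low_content_slices`
#' @export
generate_gliomap <- function(model, processed, slice_axis = 3L,
                             min_brain_fraction = 0.05,
                             mask_to_brain = TRUE) {
  cfg <- model$config
  G <- model$G
  s <- cfg$image_size
  dims <- dim(processed$brain_mask)
  inplane <- dims[-slice_axis]
  nk <- dims[slice_axis]
  enc <- array(0, dim = dims)
  failed <- integer(0)
  low <- integer(0)
  slice_of <- function(vol, k) {
    switch(slice_axis, `1` = vol[k, , ], `2` = vol[, k, ], `3` = vol[, , k])
  }
  for (k in seq_len(nk)) {
    chans <- lapply(list(processed$t1w_norm, processed$t2w_norm,
                         processed$zce$encoded),
                    function(v) quantize_8bit(fit_square(slice_of(bare(v), k), s)))
    x <- array(c(chans[[1]], chans[[2]], chans[[3]]), dim = c(s, s, 3)) / 255
    out <- gen_forward(G, x)$out[, , 1] * 255
    if (any(!is.finite(out)))
      stop(sprintf("non-finite generator output on slice %d", k))
    bm <- slice_of(bare(processed$brain_mask), k)
    if (mean(bm != 0) < min_brain_fraction) {
      low <- c(low, k)
    } else if (diff(range(out)) < cfg$range_floor) {
      failed <- c(failed, k)
    }
    full <- unfit_square(out, inplane)
    switch(slice_axis,
           `1` = { enc[k, , ] <- full },
           `2` = { enc[, k, ] <- full },
           `3` = { enc[, , k] <- full })
  }
  enc <- pmin(pmax(enc, 0), 255)
  if (mask_to_brain) enc <- enc * (bare(processed$brain_mask) != 0)
  dim(enc) <- dims
  vs <- processed$voxel_size_mm
  out <- list(encoded = as_volume(enc, vs),
              tn = as_volume(enc / 51, vs),
              subject_id = processed$subject_id,
              failed_slices = failed, low_content_slices = low)
  class(out) <- "gliomap_volume"
  out
}

#' @export
print.gliomap_volume <- function(x, ...) {
  cat(sprintf("<gliomap_volume> %s: T/N range [%.2f, %.2f], %d failed slice(s)\n",
              x$subject_id, min(x$tn), max(x$tn), length(x$failed_slices)))
  invisible(x)
}
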