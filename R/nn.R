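# Internal neural-network machinery for the compact pix2pix-style
# translator: U-Net generator, PatchGAN discriminator, manual
# backpropagation over the Rcpp conv2d primitives, and Adam.
# Tensors are (H, W, C) arrays; weights of a conv mapping C -> Cout are
# (Cout x C*16) matrices (4x4 kernels throughout, layout fixed in conv.cpp).
# Blocks follow the published layout: conv/deconv -> per-sample (instance)
# channel normalization -> LeakyReLU (encoder/discriminator) or ReLU
# (decoder); no normalization on the first encoder/discriminator layer,
# the innermost encoder layer, or the two output heads.

init_conv <- function(cout, cin, k = 4L, norm = FALSE) {
  l <- list(w = matrix(rnorm(cout * cin * k * k, 0, 0.02), cout, cin * k * k),
            b = rep(0, cout))
  if (norm) {
    l$g <- rep(1, cout)    # per-channel scale of the normalized response
    l$gb <- rep(0, cout)   # per-channel shift
  }
  l
}

lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
dlrelu <- function(pre, a = 0.2) ifelse(pre > 0, 1, a)

concat_ch <- function(a, b) {
  d <- dim(a)
  array(c(a, b), dim = c(d[1], d[2], d[3] + dim(b)[3]))
}

# per-sample, per-channel normalization over the spatial plane
norm_fwd <- function(z, g, gb, eps = 1e-5) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3])
  mu <- colMeans(m)
  inv <- 1 / sqrt(colMeans(m^2) - mu^2 + eps)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(inv, each = nrow(m))
  y <- xhat * rep(g, each = nrow(m)) + rep(gb, each = nrow(m))
  list(y = array(y, dim = d), xhat = xhat, inv = inv)
}

norm_bwd <- function(dy, cache, g) {
  d <- dim(dy)
  n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  dgb <- colSums(dym)
  dxhat <- dym * rep(g, each = n)
  dx <- rep(cache$inv, each = n) *
    (dxhat - rep(colMeans(dxhat), each = n) -
       xhat * rep(colMeans(dxhat * xhat), each = n))
  list(dx = array(dx, dim = d), dg = dg, dgb = dgb)
}

# transposed conv (x2 upsampling): forward via conv_bwd_data with the
# weight of the conv mapping out-channels -> in-channels
deconv_fwd <- function(x, layer) {
  d <- dim(x)
  y <- conv_bwd_data(x, layer$w, 4L, 4L, 2L, 1L, 2L * d[1], 2L * d[2])
  sweep(y, 3, layer$b, "+")
}

has_norm <- function(layer) !is.null(layer$g)

# --- generator (U-Net with skip connections) -------------------------------

make_generator <- function(image_size, base, in_ch = 3L, out_ch = 1L) {
  L <- as.integer(round(log2(image_size))) - 1L
  ch <- pmin(base * 2^(seq_len(L) - 1L), 8L * base)
  enc <- vector("list", L)
  enc[[1]] <- init_conv(ch[1], in_ch)
  for (i in seq_len(L)[-1]) enc[[i]] <- init_conv(ch[i], ch[i - 1],
                                                  norm = i < L)
  dec <- vector("list", L)
  for (i in L:1) {
    a <- if (i == L) ch[L] else 2L * ch[i]      # deconv input channels
    b <- if (i == 1) out_ch else ch[i - 1]      # deconv output channels
    dec[[i]] <- list(w = matrix(rnorm(a * b * 16, 0, 0.02), a, b * 16),
                     b = rep(0, b))
    if (i > 1) {
      dec[[i]]$g <- rep(1, b)
      dec[[i]]$gb <- rep(0, b)
    }
  }
  list(enc = enc, dec = dec,
       meta = list(L = L, ch = ch, in_ch = in_ch, out_ch = out_ch,
                   image_size = as.integer(image_size)))
}

# gen_forward(train = TRUE) applies inverted dropout (p = 0.5) to the
# three innermost decoder blocks, as in the published generator; masks are
# drawn from the session RNG and cached for the backward pass
gen_forward <- function(G, x, train = FALSE) {
  L <- G$meta$L
  e <- pre <- nrm <- vector("list", L)
  h <- x
  for (i in seq_len(L)) {
    z <- conv_fwd(h, G$enc[[i]]$w, G$enc[[i]]$b, 4L, 4L, 2L, 1L)
    if (has_norm(G$enc[[i]])) {
      nrm[[i]] <- norm_fwd(z, G$enc[[i]]$g, G$enc[[i]]$gb)
      pre[[i]] <- nrm[[i]]$y
    } else pre[[i]] <- z
    h <- lrelu(pre[[i]])
    e[[i]] <- h
  }
  dec_in <- dec_pre <- dec_nrm <- drop_mask <- vector("list", L)
  h <- e[[L]]
  out <- NULL
  for (i in L:1) {
    dec_in[[i]] <- h
    z <- deconv_fwd(h, G$dec[[i]])
    if (has_norm(G$dec[[i]])) {
      dec_nrm[[i]] <- norm_fwd(z, G$dec[[i]]$g, G$dec[[i]]$gb)
      z <- dec_nrm[[i]]$y
    }
    if (train && i > L - 3L && i > 1) {
      drop_mask[[i]] <- array(2 * (runif(length(z)) < 0.5), dim = dim(z))
      z <- z * drop_mask[[i]]
    }
    dec_pre[[i]] <- z
    if (i > 1) h <- concat_ch(pmax(z, 0), e[[i - 1]])
    else out <- 1 / (1 + exp(-z))               # sigmoid head -> [0, 1]
  }
  list(out = out, x = x, e = e, pre = pre, nrm = nrm, dec_in = dec_in,
       dec_pre = dec_pre, dec_nrm = dec_nrm, drop_mask = drop_mask)
}

gen_backward <- function(G, cache, dout) {
  L <- G$meta$L
  genc <- gdec <- vector("list", L)
  de <- vector("list", L)                        # grads flowing into e[[i]]
  dz <- dout * cache$out * (1 - cache$out)       # through sigmoid
  for (i in seq_len(L)) {
    # dz is the gradient at dec_pre[[i]] (post-norm/dropout where present)
    gl <- list()
    if (!is.null(cache$drop_mask[[i]])) dz <- dz * cache$drop_mask[[i]]
    if (has_norm(G$dec[[i]])) {
      nb <- norm_bwd(dz, cache$dec_nrm[[i]], G$dec[[i]]$g)
      gl$g <- nb$dg; gl$gb <- nb$dgb
      dz <- nb$dx
    }
    din <- cache$dec_in[[i]]
    gw <- conv_bwd_weight(dz, din, 4L, 4L, 2L, 1L)   # conv view: input dz
    gdec[[i]] <- c(list(w = gw$dw, b = apply(dz, 3, sum)), gl)
    gdec[[i]] <- gdec[[i]][names(G$dec[[i]])]
    dh <- conv_fwd(dz, G$dec[[i]]$w, rep(0, nrow(G$dec[[i]]$w)),
                   4L, 4L, 2L, 1L)
    if (i == L) {
      de[[L]] <- dh                              # dec_in[[L]] = e[[L]]
    } else {
      nup <- dim(cache$dec_pre[[i + 1]])[3]      # relu half of the concat
      da <- dh[, , seq_len(nup), drop = FALSE]
      de[[i]] <- dh[, , nup + seq_len(dim(dh)[3] - nup), drop = FALSE]
      dz <- da * (cache$dec_pre[[i + 1]] > 0)
    }
  }
  dcur <- de[[L]]
  for (i in L:1) {
    dz_enc <- dcur * dlrelu(cache$pre[[i]])
    gl <- list()
    if (has_norm(G$enc[[i]])) {
      nb <- norm_bwd(dz_enc, cache$nrm[[i]], G$enc[[i]]$g)
      gl$g <- nb$dg; gl$gb <- nb$dgb
      dz_enc <- nb$dx
    }
    xin <- if (i == 1) cache$x else cache$e[[i - 1]]
    gw <- conv_bwd_weight(xin, dz_enc, 4L, 4L, 2L, 1L)
    genc[[i]] <- c(list(w = gw$dw, b = gw$db), gl)
    genc[[i]] <- genc[[i]][names(G$enc[[i]])]
    if (i > 1) {
      d <- dim(cache$e[[i - 1]])
      dcur <- conv_bwd_data(dz_enc, G$enc[[i]]$w, 4L, 4L, 2L, 1L,
                            d[1], d[2])
      if (!is.null(de[[i - 1]])) dcur <- dcur + de[[i - 1]]
    }
  }
  list(enc = genc, dec = gdec)
}

# --- discriminator (PatchGAN) ----------------------------------------------

make_discriminator <- function(base, in_ch = 4L) {
  ch <- c(base, 2L * base, 4L * base, 8L * base, 1L)
  st <- c(2L, 2L, 2L, 1L, 1L)
  layers <- vector("list", 5L)
  cin <- in_ch
  for (i in 1:5) {
    layers[[i]] <- init_conv(ch[i], cin, norm = i %in% 2:4)
    cin <- ch[i]
  }
  list(layers = layers, meta = list(ch = ch, st = st, in_ch = in_ch))
}

disc_forward <- function(D, x) {
  st <- D$meta$st
  ins <- pre <- nrm <- vector("list", 5L)
  h <- x
  for (i in 1:5) {
    ins[[i]] <- h
    z <- conv_fwd(h, D$layers[[i]]$w, D$layers[[i]]$b, 4L, 4L, st[i], 1L)
    if (has_norm(D$layers[[i]])) {
      nrm[[i]] <- norm_fwd(z, D$layers[[i]]$g, D$layers[[i]]$gb)
      z <- nrm[[i]]$y
    }
    pre[[i]] <- z
    h <- if (i < 5) lrelu(z) else z
  }
  list(out = h, ins = ins, pre = pre, nrm = nrm)   # out = patch logits
}

disc_backward <- function(D, cache, dz_out) {
  st <- D$meta$st
  grads <- vector("list", 5L)
  dz <- dz_out
  for (i in 5:1) {
    if (i < 5) dz <- dz * dlrelu(cache$pre[[i]])
    gl <- list()
    if (has_norm(D$layers[[i]])) {
      nb <- norm_bwd(dz, cache$nrm[[i]], D$layers[[i]]$g)
      gl$g <- nb$dg; gl$gb <- nb$dgb
      dz <- nb$dx
    }
    gw <- conv_bwd_weight(cache$ins[[i]], dz, 4L, 4L, st[i], 1L)
    grads[[i]] <- c(list(w = gw$dw, b = gw$db), gl)
    grads[[i]] <- grads[[i]][names(D$layers[[i]])]
    d <- dim(cache$ins[[i]])
    dz <- conv_bwd_data(dz, D$layers[[i]]$w, 4L, 4L, st[i], 1L, d[1], d[2])
  }
  list(grads = list(layers = grads), dx = dz)
}

# --- losses ----------------------------------------------------------------

# numerically stable binary cross-entropy with logits, mean over patches
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}
bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}

# --- parameter-tree utilities and Adam -------------------------------------

tree_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
  out
}

tree_zero <- function(a) {
  if (is.numeric(a)) return(a * 0)
  out <- a
  for (i in seq_along(a)) out[[i]] <- tree_zero(a[[i]])
  out
}

tree_add <- function(a, b) tree_map2(a, b, `+`)
tree_scale <- function(a, s) tree_map2(a, a, function(x, y) x * s)

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}
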