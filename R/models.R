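# The four inpainting architectures. Feature maps are H x W x C arrays;
# convolution weights are C_out x (C_in*k*k) matrices acting on im2col
# unfoldings (compiled kernels in src/). Every architecture is a
# shape-preserving 1-channel -> 1-channel map with a linear (unclamped)
# output; forward passes cache the intermediates needed for the hand-derived
# backward passes, which are verified against finite differences in the test
# suite. No normalisation layers are used anywhere: parameter counts stay
# exactly those of the convolutions.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

he_init <- function(cout, cin, k) {
  matrix(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
         cout, cin * k * k)
}

conv_param <- function(cout, cin, k) list(w = he_init(cout, cin, k),
                                          b = numeric(cout))

round_half_up <- function(x) floor(x + 0.5)

#' Channel schedule of a tunable U-Net
#'
#' Channels at resolution level `d` (0-based) are
#' `round(base_channels * growth_rate^d)`, rounded half away from zero to
#' accommodate fractional growth rates such as 1.5 or 2.5.
#'
#' @param base_channels channels at the top level.
#' @param growth_rate channel growth per contraction.
#' @param depth number of resolution levels.
#' @return Integer vector of length `depth`.
#' @export
tunet_channels <- function(base_channels, growth_rate, depth) {
  as.integer(round_half_up(base_channels * growth_rate^(seq_len(depth) - 1)))
}

new_net <- function(arch, cfg, params) {
  structure(list(arch = arch, cfg = cfg, params = params),
            class = c(arch, "inpaint_net"))
}

#' Build a convolutional autoencoder
#'
#' A symmetric encoder-decoder without skip connections: each encoder stage
#' is a 3x3 convolution + ReLU followed by 2x2 max-pooling (channels double
#' per stage from `base_channels`); the decoder alternates 3x3 convolutions
#' and 2x2 stride-2 transposed convolutions back to full resolution, ending
#' in a linear 3x3 convolution to one channel. The latent representation is
#' a spatial feature map (no dense bottleneck). Inputs must be divisible by
#' `2^depth` in both dimensions.
#'
#' @param depth number of pooling stages.
#' @param base_channels channels of the first stage.
#' @param seed seed for weight initialisation.
#' @return An `inpaint_net` of architecture `"autoencoder"`.
#' @export
build_autoencoder <- function(depth = 2L, base_channels = 32L, seed = 1L) {
  if (depth < 1L || base_channels < 1L)
    stop("depth and base_channels must be at least 1")
  ch <- base_channels * 2L^(seq_len(depth) - 1L)
  params <- list()
  with_seed(seed, {
    prev <- 1L
    for (s in seq_len(depth)) {
      params[[paste0("enc", s)]] <- conv_param(ch[s], prev, 3L)
      prev <- ch[s]
    }
    for (s in rev(seq_len(depth))) {
      cprev <- if (s > 1L) ch[s - 1L] else base_channels
      params[[paste0("dec", s)]] <- conv_param(ch[s], ch[s], 3L)
      params[[paste0("up", s)]] <- conv_param(cprev, ch[s], 2L)
    }
    params$out <- conv_param(1L, base_channels, 3L)
  })
  new_net("autoencoder", list(depth = as.integer(depth),
                              base_channels = as.integer(base_channels),
                              channels = ch), params)
}

#' Build a tunable U-Net
#'
#' A U-Net whose depth (resolution levels), initial channel count and
#' channel growth rate are free hyperparameters. Each level applies two 3x3
#' convolutions with ReLU; contraction is 2x2 max-pooling, expansion is a
#' 2x2 stride-2 transposed convolution whose output is concatenated
#' channel-wise with the mirrored encoder features; a final 1x1 convolution
#' maps to one channel. Inputs must be divisible by `2^(depth-1)`.
#'
#' @param depth resolution levels (>= 2).
#' @param base_channels channels at the top level.
#' @param growth_rate channel growth per level (>= 1, may be fractional).
#' @param seed seed for weight initialisation.
#' @return An `inpaint_net` of architecture `"tunet"`.
#' @export
build_tunet <- function(depth = 4L, base_channels = 64L, growth_rate = 2,
                        seed = 1L) {
  if (depth < 2L) stop("a U-Net needs at least 2 resolution levels")
  if (growth_rate < 1) stop("growth_rate must be >= 1")
  ch <- tunet_channels(base_channels, growth_rate, depth)
  params <- list()
  with_seed(seed, {
    prev <- 1L
    for (l in seq_len(depth)) {
      params[[paste0("encA", l)]] <- conv_param(ch[l], prev, 3L)
      params[[paste0("encB", l)]] <- conv_param(ch[l], ch[l], 3L)
      prev <- ch[l]
    }
    for (l in rev(seq_len(depth - 1L))) {
      params[[paste0("up", l)]] <- conv_param(ch[l], ch[l + 1L], 2L)
      params[[paste0("decA", l)]] <- conv_param(ch[l], 2L * ch[l], 3L)
      params[[paste0("decB", l)]] <- conv_param(ch[l], ch[l], 3L)
    }
    params$out <- conv_param(1L, ch[1L], 1L)
  })
  new_net("tunet", list(depth = as.integer(depth),
                        base_channels = as.integer(base_channels),
                        growth_rate = growth_rate, channels = ch), params)
}

#' Build a partial-convolution U-Net
#'
#' Same topology as [build_tunet()] with growth rate 2, but every
#' convolution is a partial convolution: the layer sees only valid (non-gap)
#' pixels, renormalises its output by `kernel size / valid count`, and emits
#' an updated validity mask in which any pixel with at least one valid
#' neighbour becomes valid, so gaps shrink layer by layer. The mask stream
#' is max-pooled on contraction and nearest-upsampled on expansion;
#' expansion uses nearest upsampling followed by a partial 3x3 convolution.
#' The forward pass requires the validity mask (1 = valid, 0 = gap): this is
#' not a blind inpainting architecture.
#'
#' @param depth resolution levels (>= 2).
#' @param base_channels channels at the top level.
#' @param seed seed for weight initialisation.
#' @return An `inpaint_net` of architecture `"pconv_unet"`.
#' @export
build_partialconv_unet <- function(depth = 5L, base_channels = 32L,
                                   seed = 1L) {
  if (depth < 2L) stop("a U-Net needs at least 2 resolution levels")
  ch <- tunet_channels(base_channels, 2, depth)
  params <- list()
  with_seed(seed, {
    prev <- 1L
    for (l in seq_len(depth)) {
      params[[paste0("encA", l)]] <- conv_param(ch[l], prev, 3L)
      params[[paste0("encB", l)]] <- conv_param(ch[l], ch[l], 3L)
      prev <- ch[l]
    }
    for (l in rev(seq_len(depth - 1L))) {
      params[[paste0("up", l)]] <- conv_param(ch[l], ch[l + 1L], 3L)
      params[[paste0("decA", l)]] <- conv_param(ch[l], 2L * ch[l], 3L)
      params[[paste0("decB", l)]] <- conv_param(ch[l], ch[l], 3L)
    }
    params$out <- conv_param(1L, ch[1L], 1L)
  })
  new_net("pconv_unet", list(depth = as.integer(depth),
                             base_channels = as.integer(base_channels),
                             channels = ch), params)
}

#' Build a mixed-scale dense network
#'
#' Every layer computes a single feature channel by a 3x3 convolution (with
#' bias and ReLU) over the concatenation of the input channel and all
#' previous layer outputs; scale diversity comes from cycling the integer
#' dilation of layer `i` through `((i-1) mod max_dilation) + 1` instead of
#' pooling, so spatial dimensions are preserved throughout. The output is a
#' 1x1 convolution (with bias) over the input plus all layer channels. With
#' width 1 the trainable parameter count is exactly
#' `4.5 d^2 + 6.5 d + 2` for `d` layers.
#'
#' @param num_layers number of dense layers.
#' @param max_dilation largest dilation in the cycle.
#' @param width channels per layer; only the canonical width 1 is supported.
#' @param seed seed for weight initialisation.
#' @return An `inpaint_net` of architecture `"msdnet"`.
#' @export
build_msdnet <- function(num_layers = 100L, max_dilation = 12L, width = 1L,
                         seed = 1L) {
  if (num_layers < 1L || max_dilation < 1L)
    stop("num_layers and max_dilation must be at least 1")
  if (width != 1L) stop("only width 1 is supported")
  dil <- ((seq_len(num_layers) - 1L) %% max_dilation) + 1L
  params <- list(layers = vector("list", num_layers))
  with_seed(seed, {
    for (i in seq_len(num_layers))
      params$layers[[i]] <- list(w = he_init(1L, i, 3L), b = 0)
    params$out <- list(w = matrix(stats::rnorm(num_layers + 1L,
                                               sd = sqrt(1 / (num_layers + 1))),
                                  1L, num_layers + 1L),
                       b = 0)
  })
  new_net("msdnet", list(num_layers = as.integer(num_layers),
                         max_dilation = as.integer(max_dilation),
                         width = 1L, dilations = dil), params)
}

#' Partial convolution of a single patch
#'
#' The defining local operation of the partial-convolution layer: given a
#' patch `x`, a binary validity mask `m` and a kernel `W` of the same
#' extent, the output is `sum(W * (x * m)) * (|W| / sum(m)) + b` with
#' updated mask bit 1 when the window holds at least one valid cell, and
#' `(0, 0)` otherwise (`|W|` is the kernel element count).
#'
#' @param x numeric patch.
#' @param m binary mask of the same extent.
#' @param w kernel weights of the same extent.
#' @param b bias.
#' @return List with scalar `y` and updated mask bit `m_new`.
#' @export
partial_conv <- function(x, m, w, b = 0) {
  if (!identical(dim(x), dim(m)) || !identical(dim(x), dim(w)))
    stop("patch, mask and kernel extents must agree")
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  s <- sum(m)
  if (s == 0) return(list(y = 0, m_new = 0))
  list(y = sum(w * (x * m)) * (length(w) / s) + b, m_new = 1)
}

#' Count trainable parameters of a network
#'
#' @param net an `inpaint_net`.
#' @return Total number of trainable scalars.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "inpaint_net"))
  n <- 0L
  walk <- function(p) {
    for (el in p) {
      if (is.list(el)) walk(el) else n <<- n + length(el)
    }
  }
  walk(net$params)
  n
}

check_divisible <- function(x, pow) {
  if (nrow(x) %% 2L^pow != 0L || ncol(x) %% 2L^pow != 0L)
    stop(sprintf("input dimensions %d x %d must be divisible by %d",
                 nrow(x), ncol(x), 2L^pow))
}

relu_fw <- function(x) { x[x < 0] <- 0; x }

# ---- forward/backward passes -----------------------------------------------

forward_autoencoder <- function(net, x) {
  p <- net$params; depth <- net$cfg$depth
  check_divisible(x, depth)
  cache <- list(x = as_cube(x), enc = list(), pool = list(), dec = list(),
                up = list())
  h <- cache$x
  for (s in seq_len(depth)) {
    pr <- p[[paste0("enc", s)]]
    a <- relu_fw(conv2d_fw(h, pr$w, pr$b, 3L, 1L))
    cache$enc[[s]] <- list(input = h, act = a)
    mp <- maxpool_fw(a)
    cache$pool[[s]] <- list(idx = mp$idx, H = nrow(a), W = ncol(a))
    h <- mp$y
  }
  cache$latent <- h
  for (s in rev(seq_len(depth))) {
    pr <- p[[paste0("dec", s)]]
    a <- relu_fw(conv2d_fw(h, pr$w, pr$b, 3L, 1L))
    cache$dec[[s]] <- list(input = h, act = a)
    pu <- p[[paste0("up", s)]]
    u <- relu_fw(upconv_fw(a, pu$w, pu$b))
    cache$up[[s]] <- list(input = a, act = u)
    h <- u
  }
  cache$outin <- h
  y <- conv2d_fw(h, p$out$w, p$out$b, 3L, 1L)
  list(y = y[, , 1L], cache = cache)
}

backward_autoencoder <- function(net, cache, dy) {
  p <- net$params; depth <- net$cfg$depth
  g <- list()
  bw <- conv2d_bw(cache$outin, p$out$w, as_cube(dy), 3L, 1L)
  g$out <- list(w = bw$dw, b = bw$db)
  d <- bw$dx
  for (s in seq_len(depth)) {
    up <- cache$up[[s]]
    d <- d * (up$act > 0)
    pu <- p[[paste0("up", s)]]
    bw <- upconv_bw(up$input, pu$w, d)
    g[[paste0("up", s)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
    dc <- cache$dec[[s]]
    d <- d * (dc$act > 0)
    pr <- p[[paste0("dec", s)]]
    bw <- conv2d_bw(dc$input, pr$w, d, 3L, 1L)
    g[[paste0("dec", s)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  for (s in rev(seq_len(depth))) {
    pl <- cache$pool[[s]]
    d <- maxpool_bw(pl$idx, d, pl$H, pl$W)
    en <- cache$enc[[s]]
    d <- d * (en$act > 0)
    pr <- p[[paste0("enc", s)]]
    bw <- conv2d_bw(en$input, pr$w, d, 3L, 1L)
    g[[paste0("enc", s)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  g
}

forward_tunet <- function(net, x) {
  p <- net$params; depth <- net$cfg$depth
  check_divisible(x, depth - 1L)
  cache <- list(enc = list(), pool = list(), up = list(), dec = list())
  h <- as_cube(x)
  for (l in seq_len(depth)) {
    a <- p[[paste0("encA", l)]]
    ya <- relu_fw(conv2d_fw(h, a$w, a$b, 3L, 1L))
    b <- p[[paste0("encB", l)]]
    yb <- relu_fw(conv2d_fw(ya, b$w, b$b, 3L, 1L))
    cache$enc[[l]] <- list(input = h, actA = ya, actB = yb)
    if (l < depth) {
      mp <- maxpool_fw(yb)
      cache$pool[[l]] <- list(idx = mp$idx, H = nrow(yb), W = ncol(yb))
      h <- mp$y
    } else h <- yb
  }
  for (l in rev(seq_len(depth - 1L))) {
    pu <- p[[paste0("up", l)]]
    u <- relu_fw(upconv_fw(h, pu$w, pu$b))
    skip <- cache$enc[[l]]$actB
    cat_in <- array(c(skip, u), c(dim(skip)[1:2], dim(skip)[3] + dim(u)[3]))
    a <- p[[paste0("decA", l)]]
    ya <- relu_fw(conv2d_fw(cat_in, a$w, a$b, 3L, 1L))
    b <- p[[paste0("decB", l)]]
    yb <- relu_fw(conv2d_fw(ya, b$w, b$b, 3L, 1L))
    cache$up[[l]] <- list(input = h, act = u)
    cache$dec[[l]] <- list(cat = cat_in, actA = ya, actB = yb)
    h <- yb
  }
  cache$outin <- h
  y <- conv2d_fw(h, p$out$w, p$out$b, 1L, 1L)
  list(y = y[, , 1L], cache = cache)
}

backward_tunet <- function(net, cache, dy) {
  p <- net$params; depth <- net$cfg$depth
  g <- list()
  bw <- conv2d_bw(cache$outin, p$out$w, as_cube(dy), 1L, 1L)
  g$out <- list(w = bw$dw, b = bw$db)
  d <- bw$dx
  dskip <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    dc <- cache$dec[[l]]
    d <- d * (dc$actB > 0)
    b <- p[[paste0("decB", l)]]
    bw <- conv2d_bw(dc$actA, b$w, d, 3L, 1L)
    g[[paste0("decB", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx * (dc$actA > 0)
    a <- p[[paste0("decA", l)]]
    bw <- conv2d_bw(dc$cat, a$w, d, 3L, 1L)
    g[[paste0("decA", l)]] <- list(w = bw$dw, b = bw$db)
    nsk <- dim(cache$enc[[l]]$actB)[3]
    dskip[[l]] <- bw$dx[, , seq_len(nsk), drop = FALSE]
    du <- bw$dx[, , nsk + seq_len(dim(bw$dx)[3] - nsk), drop = FALSE]
    up <- cache$up[[l]]
    du <- du * (up$act > 0)
    pu <- p[[paste0("up", l)]]
    bw <- upconv_bw(up$input, pu$w, du)
    g[[paste0("up", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      pl <- cache$pool[[l]]
      d <- maxpool_bw(pl$idx, d, pl$H, pl$W)
      d <- d + dskip[[l]]
    }
    en <- cache$enc[[l]]
    d <- d * (en$actB > 0)
    b <- p[[paste0("encB", l)]]
    bw <- conv2d_bw(en$actA, b$w, d, 3L, 1L)
    g[[paste0("encB", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx * (en$actA > 0)
    a <- p[[paste0("encA", l)]]
    bw <- conv2d_bw(en$input, a$w, d, 3L, 1L)
    g[[paste0("encA", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  g
}

pconv_block <- function(h, m, pr, k) {
  out <- pconv2d_fw(h, m, pr$w, pr$b, k, 1L)
  out$y <- relu_fw(out$y)
  out
}

forward_pconv <- function(net, x, mask) {
  if (is.null(mask))
    stop("the partial-convolution network requires the validity mask")
  p <- net$params; depth <- net$cfg$depth
  check_divisible(x, depth - 1L)
  if (!all(mask %in% c(0, 1))) stop("validity mask must be binary")
  cache <- list(enc = list(), pool = list(), up = list(), dec = list())
  h <- as_cube(x); m <- mask
  for (l in seq_len(depth)) {
    a <- p[[paste0("encA", l)]]
    fa <- pconv2d_fw(h, m, a$w, a$b, 3L, 1L)
    ya <- relu_fw(fa$y)
    b <- p[[paste0("encB", l)]]
    fb <- pconv2d_fw(ya, fa$mask, b$w, b$b, 3L, 1L)
    yb <- relu_fw(fb$y)
    cache$enc[[l]] <- list(input = h, m_in = m, fa = fa, actA = ya,
                           fb = fb, actB = yb)
    m <- fb$mask
    if (l < depth) {
      mp <- maxpool_fw(yb)
      cache$pool[[l]] <- list(idx = mp$idx, H = nrow(yb), W = ncol(yb))
      h <- mp$y
      m <- maxpool_fw(array(m, c(dim(m), 1L)))$y[, , 1L]
    } else h <- yb
  }
  for (l in rev(seq_len(depth - 1L))) {
    # nearest upsample features and mask, partial conv to the level width
    hu <- array(0, c(2L * dim(h)[1], 2L * dim(h)[2], dim(h)[3]))
    for (c in seq_len(dim(h)[3])) hu[, , c] <- upsample2_nn(h[, , c])
    mu <- upsample2_nn(m)
    pu <- p[[paste0("up", l)]]
    fu <- pconv2d_fw(hu, mu, pu$w, pu$b, 3L, 1L)
    u <- relu_fw(fu$y)
    skip <- cache$enc[[l]]$actB
    mskip <- cache$enc[[l]]$fb$mask
    cat_in <- array(c(skip, u), c(dim(skip)[1:2], dim(skip)[3] + dim(u)[3]))
    mcat <- pmax(mskip, fu$mask)
    a <- p[[paste0("decA", l)]]
    fA <- pconv2d_fw(cat_in, mcat, a$w, a$b, 3L, 1L)
    ya <- relu_fw(fA$y)
    b <- p[[paste0("decB", l)]]
    fB <- pconv2d_fw(ya, fA$mask, b$w, b$b, 3L, 1L)
    yb <- relu_fw(fB$y)
    cache$up[[l]] <- list(hu = hu, mu = mu, fu = fu, act = u)
    cache$dec[[l]] <- list(cat = cat_in, mcat = mcat, fA = fA, actA = ya,
                           fB = fB, actB = yb)
    h <- yb; m <- fB$mask
  }
  cache$outin <- h; cache$outmask <- m
  fo <- pconv2d_fw(h, m, p$out$w, p$out$b, 1L, 1L)
  list(y = fo$y[, , 1L], cache = cache, mask_out = fo$mask)
}

backward_pconv <- function(net, cache, dy) {
  p <- net$params; depth <- net$cfg$depth
  g <- list()
  bw <- pconv2d_bw(cache$outin, cache$outmask,
                   matrix(1, nrow(cache$outmask), ncol(cache$outmask)) *
                     (cache$outmask > 0),
                   p$out$w, as_cube(dy), 1L, 1L)
  # scale for a 1x1 pconv is 1 on valid pixels, 0 elsewhere
  g$out <- list(w = bw$dw, b = bw$db)
  d <- bw$dx
  dskip <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    dc <- cache$dec[[l]]
    d <- d * (dc$actB > 0)
    b <- p[[paste0("decB", l)]]
    bw <- pconv2d_bw(dc$actA, dc$fA$mask, dc$fB$scale, b$w, d, 3L, 1L)
    g[[paste0("decB", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx * (dc$actA > 0)
    a <- p[[paste0("decA", l)]]
    bw <- pconv2d_bw(dc$cat, dc$mcat, dc$fA$scale, a$w, d, 3L, 1L)
    g[[paste0("decA", l)]] <- list(w = bw$dw, b = bw$db)
    nsk <- dim(cache$enc[[l]]$actB)[3]
    dskip[[l]] <- bw$dx[, , seq_len(nsk), drop = FALSE]
    du <- bw$dx[, , nsk + seq_len(dim(bw$dx)[3] - nsk), drop = FALSE]
    up <- cache$up[[l]]
    du <- du * (up$act > 0)
    pu <- p[[paste0("up", l)]]
    bw <- pconv2d_bw(up$hu, up$mu, up$fu$scale, pu$w, du, 3L, 1L)
    g[[paste0("up", l)]] <- list(w = bw$dw, b = bw$db)
    # adjoint of nearest upsampling: sum each 2x2 block
    dh <- bw$dx
    d <- array(0, c(dim(dh)[1] / 2L, dim(dh)[2] / 2L, dim(dh)[3]))
    for (c in seq_len(dim(dh)[3])) {
      s <- dh[, , c]
      d[, , c] <- s[c(TRUE, FALSE), c(TRUE, FALSE)] +
        s[c(FALSE, TRUE), c(TRUE, FALSE)] +
        s[c(TRUE, FALSE), c(FALSE, TRUE)] +
        s[c(FALSE, TRUE), c(FALSE, TRUE)]
    }
  }
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      pl <- cache$pool[[l]]
      d <- maxpool_bw(pl$idx, d, pl$H, pl$W)
      d <- d + dskip[[l]]
    }
    en <- cache$enc[[l]]
    d <- d * (en$actB > 0)
    b <- p[[paste0("encB", l)]]
    bw <- pconv2d_bw(en$actA, en$fa$mask, en$fb$scale, b$w, d, 3L, 1L)
    g[[paste0("encB", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx * (en$actA > 0)
    a <- p[[paste0("encA", l)]]
    bw <- pconv2d_bw(en$input, en$m_in, en$fa$scale, a$w, d, 3L, 1L)
    g[[paste0("encA", l)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  g
}

forward_msdnet <- function(net, x) {
  p <- net$params
  ws <- lapply(p$layers, `[[`, "w")
  bs <- lapply(p$layers, `[[`, "b")
  f <- msd_fw(x, ws, bs, net$cfg$dilations, as.numeric(p$out$w), p$out$b)
  list(y = f$out, cache = f$stack)
}

backward_msdnet <- function(net, cache, dy) {
  p <- net$params
  ws <- lapply(p$layers, `[[`, "w")
  bw <- msd_bw(cache, ws, net$cfg$dilations, as.numeric(p$out$w), dy)
  list(layers = lapply(seq_along(ws), function(i)
         list(w = bw$dws[[i]], b = bw$dbs[[i]])),
       out = list(w = matrix(bw$dwout, 1L), b = bw$dbout))
}

#' Run a network forward
#'
#' @param net an `inpaint_net`.
#' @param x input frame/strip (numeric matrix).
#' @param mask validity mask (1 = valid), required for the
#'   partial-convolution architecture and ignored by the blind ones.
#' @param want_cache keep the intermediates needed for [net_backward()].
#' @return List with `y` (output matrix) and, if requested, `cache`.
#' @export
net_forward <- function(net, x, mask = NULL, want_cache = FALSE) {
  stopifnot(inherits(net, "inpaint_net"))
  out <- switch(net$arch,
                autoencoder = forward_autoencoder(net, x),
                tunet = forward_tunet(net, x),
                pconv_unet = forward_pconv(net, x, mask),
                msdnet = forward_msdnet(net, x),
                stop("unknown architecture"))
  if (!want_cache) out$cache <- NULL
  out
}

#' Backpropagate through a network
#'
#' @param net an `inpaint_net`.
#' @param cache the cache from `net_forward(..., want_cache = TRUE)`.
#' @param dy gradient of the loss with respect to the output.
#' @return Named list of gradients mirroring `net$params`.
#' @export
net_backward <- function(net, cache, dy) {
  switch(net$arch,
         autoencoder = backward_autoencoder(net, cache, dy),
         tunet = backward_tunet(net, cache, dy),
         pconv_unet = backward_pconv(net, cache, dy),
         msdnet = backward_msdnet(net, cache, dy),
         stop("unknown architecture"))
}

#' @export
predict.inpaint_net <- function(object, x, mask = NULL, ...) {
  net_forward(object, x, mask = mask)$y
}

#' @export
print.inpaint_net <- function(x, ...) {
  cat(sprintf("<%s: %s; %d trainable parameters>\n", x$arch,
              paste(names(x$cfg)[1:2], unlist(x$cfg[1:2]), sep = "=",
                    collapse = ", "),
              count_parameters(x)))
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Weights and configuration are stored together so a checkpoint reloads
#' into an identical network.
#'
#' @param net an `inpaint_net`.
#' @param path file path (`.rds`).
#' @return `save_net` returns `path` invisibly; `load_net` the network.
#' @export
save_net <- function(net, path) {
  stopifnot(inherits(net, "inpaint_net"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_net
#' @export
load_net <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "inpaint_net"))
  net
}
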