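# Latent-space quality analysis: masked, ground-truth and inpainted image
# sets are each embedded with identically configured reconstruction-trained
# autoencoders (convolutional encoder, global average pooling, dense
# projection to exactly 200 dimensions), and inpainting quality is assessed
# by how well neighbourhood structure in the ground-truth space is
# preserved: Pearson correlation between an image and its rank-r latent
# neighbour, and the overlap of 100-nearest-neighbour sets.

emb_channels <- c(8L, 16L, 16L)

#' Train an embedding autoencoder
#'
#' Frames are resampled to `input_size` and passed through three
#' convolution + ReLU + max-pool stages, globally average-pooled and densely
#' projected to a `dim`-dimensional latent vector; a mirrored decoder
#' (dense, reshape, alternating transposed and plain convolutions)
#' reconstructs the frame, and the whole model is trained with L1
#' reconstruction loss under ADAM. Comparable latent spaces require
#' identical `cfg`, `seed`, `dim` and `input_size` across the image sets
#' being compared. `total_epochs = 0` yields the seeded random-init encoder.
#'
#' @param images list of square frames.
#' @param dim latent dimension; 200 is the reference value, other values
#'   are accepted with a warning.
#' @param cfg a [train_config()] (only `lr_*`, `total_epochs`, `batch_size`
#'   and `seed` are used).
#' @param seed weight-initialisation seed.
#' @param input_size working resolution of the embedding network (frames
#'   are bicubically resampled to this size; multiple of 8).
#' @return An object of class `frame_encoder`.
#' @export
train_embedding <- function(images, dim = 200L,
                            cfg = train_config(total_epochs = 10L,
                                               lr_step = 10L,
                                               batch_size = 8L),
                            seed = 1L, input_size = 64L) {
  dim <- as.integer(dim)
  if (dim != 200L)
    warning("latent dimension differs from the reference value of 200")
  input_size <- as.integer(input_size)
  if (input_size %% 8L != 0L) stop("input_size must be a multiple of 8")
  ch <- emb_channels
  s8 <- input_size %/% 8L
  params <- list()
  with_seed(seed, {
    prev <- 1L
    for (s in 1:3) {
      params[[paste0("enc", s)]] <- conv_param(ch[s], prev, 3L)
      prev <- ch[s]
    }
    params$proj <- list(w = matrix(stats::rnorm(dim * ch[3],
                                                sd = sqrt(1 / ch[3])),
                                   dim, ch[3]), b = numeric(dim))
    params$dproj <- list(w = matrix(stats::rnorm(s8 * s8 * 8L * dim,
                                                 sd = sqrt(1 / dim)),
                                    s8 * s8 * 8L, dim),
                         b = numeric(s8 * s8 * 8L))
    params$dup3 <- conv_param(8L, 8L, 2L)
    params$dconv3 <- conv_param(8L, 8L, 3L)
    params$dup2 <- conv_param(8L, 8L, 2L)
    params$dconv2 <- conv_param(8L, 8L, 3L)
    params$dup1 <- conv_param(4L, 8L, 2L)
    params$dconv1 <- conv_param(1L, 4L, 3L)
  })
  enc <- structure(list(params = params, dim = dim,
                        input_size = input_size, s8 = s8),
                   class = "frame_encoder")
  if (cfg$total_epochs == 0L) return(enc)

  xs <- lapply(images, function(im) {
    if (nrow(im) != input_size || ncol(im) != input_size)
      im <- resize_bicubic(im, input_size, input_size)
    im
  })
  state <- adam_init(params)
  n <- length(xs)
  for (epoch in seq_len(cfg$total_epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    ord <- with_seed(cfg$seed + 5000L + epoch, sample(n))
    b <- 1L
    while (b <= n) {
      bidx <- ord[b:min(b + cfg$batch_size - 1L, n)]
      acc <- NULL
      for (i in bidx) {
        enc$params <- params
        f <- emb_forward(enc, xs[[i]], want_cache = TRUE)
        resid <- f$recon - xs[[i]]
        dy <- sign(resid) / length(resid)
        if (!is.finite(mean(resid)))
          stop(sprintf("non-finite embedding loss at epoch %d", epoch))
        acc <- grad_accum(acc, emb_backward(enc, f$cache, dy),
                          1 / length(bidx))
      }
      st <- adam_step(params, acc, state, lr)
      params <- st$params; state <- st$state
      b <- b + cfg$batch_size
    }
  }
  enc$params <- params
  enc
}

emb_forward <- function(enc, x, want_cache = FALSE) {
  p <- enc$params
  cache <- list(enc = list(), pool = list())
  h <- as_cube(x)
  for (s in 1:3) {
    pr <- p[[paste0("enc", s)]]
    a <- relu_fw(conv2d_fw(h, pr$w, pr$b, 3L, 1L))
    cache$enc[[s]] <- list(input = h, act = a)
    mp <- maxpool_fw(a)
    cache$pool[[s]] <- list(idx = mp$idx, H = nrow(a), W = ncol(a))
    h <- mp$y
  }
  cache$gap_in <- h
  g <- apply(h, 3L, mean)                      # global average pooling
  z <- as.numeric(p$proj$w %*% g + p$proj$b)   # latent vector
  out <- list(latent = z)
  dv <- as.numeric(p$dproj$w %*% z + p$dproj$b)
  dv <- pmax(dv, 0)
  cache$g <- g; cache$z <- z; cache$dv <- dv
  hd <- array(dv, c(enc$s8, enc$s8, 8L))
  u3 <- relu_fw(upconv_fw(hd, p$dup3$w, p$dup3$b))
  c3 <- relu_fw(conv2d_fw(u3, p$dconv3$w, p$dconv3$b, 3L, 1L))
  u2 <- relu_fw(upconv_fw(c3, p$dup2$w, p$dup2$b))
  c2 <- relu_fw(conv2d_fw(u2, p$dconv2$w, p$dconv2$b, 3L, 1L))
  u1 <- relu_fw(upconv_fw(c2, p$dup1$w, p$dup1$b))
  recon <- conv2d_fw(u1, p$dconv1$w, p$dconv1$b, 3L, 1L)
  cache$dec <- list(hd = hd, u3 = u3, c3 = c3, u2 = u2, c2 = c2, u1 = u1)
  out$recon <- recon[, , 1L]
  if (want_cache) out$cache <- cache
  out
}

emb_backward <- function(enc, cache, dy) {
  p <- enc$params; g <- list(); dc <- cache$dec
  bw <- conv2d_bw(dc$u1, p$dconv1$w, as_cube(dy), 3L, 1L)
  g$dconv1 <- list(w = bw$dw, b = bw$db)
  d <- bw$dx * (dc$u1 > 0)
  bw <- upconv_bw(dc$c2, p$dup1$w, d)
  g$dup1 <- list(w = bw$dw, b = bw$db)
  d <- bw$dx * (dc$c2 > 0)
  bw <- conv2d_bw(dc$u2, p$dconv2$w, d, 3L, 1L)
  g$dconv2 <- list(w = bw$dw, b = bw$db)
  d <- bw$dx * (dc$u2 > 0)
  bw <- upconv_bw(dc$c3, p$dup2$w, d)
  g$dup2 <- list(w = bw$dw, b = bw$db)
  d <- bw$dx * (dc$c3 > 0)
  bw <- conv2d_bw(dc$u3, p$dconv3$w, d, 3L, 1L)
  g$dconv3 <- list(w = bw$dw, b = bw$db)
  d <- bw$dx * (dc$u3 > 0)
  bw <- upconv_bw(dc$hd, p$dup3$w, d)
  g$dup3 <- list(w = bw$dw, b = bw$db)
  ddv <- as.numeric(bw$dx) * (cache$dv > 0)
  g$dproj <- list(w = outer(ddv, cache$z), b = ddv)
  dz <- as.numeric(crossprod(p$dproj$w, ddv))
  g$proj <- list(w = outer(dz, cache$g), b = dz)
  dg <- as.numeric(crossprod(p$proj$w, dz))
  hin <- cache$gap_in
  npix <- dim(hin)[1] * dim(hin)[2]
  d <- array(rep(dg / npix, each = npix), dim(hin))
  for (s in 3:1) {
    pl <- cache$pool[[s]]
    d <- maxpool_bw(pl$idx, d, pl$H, pl$W)
    en <- cache$enc[[s]]
    d <- d * (en$act > 0)
    pr <- enc$params[[paste0("enc", s)]]
    bw <- conv2d_bw(en$input, pr$w, d, 3L, 1L)
    g[[paste0("enc", s)]] <- list(w = bw$dw, b = bw$db)
    d <- bw$dx
  }
  g
}

#' Embed frames into the latent space
#'
#' @param encoder a `frame_encoder`.
#' @param images list of square frames (any size; resampled internally).
#' @param image_ids identifiers aligned with `images`.
#' @param source_tag one of `"masked"`, `"truth"`, `"inpainted"` (free-form
#'   tags are allowed).
#' @return A `latent_space`: list with `vectors` (N x dim matrix),
#'   `image_ids`, `source_tag`.
#' @export
embed_frames <- function(encoder, images, image_ids = seq_along(images),
                         source_tag = "masked") {
  stopifnot(inherits(encoder, "frame_encoder"))
  V <- t(vapply(images, function(im) {
    if (nrow(im) != encoder$input_size || ncol(im) != encoder$input_size)
      im <- resize_bicubic(im, encoder$input_size, encoder$input_size)
    emb_forward(encoder, im)$latent
  }, numeric(encoder$dim)))
  structure(list(vectors = V, image_ids = image_ids,
                 source_tag = source_tag), class = "latent_space")
}

neighbor_order <- function(V) {
  D <- as.matrix(stats::dist(V))
  n <- nrow(D)
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(D[i, others], others)]   # ties broken by ascending id
  })
}

#' Mean pixel correlation by latent neighbour rank
#'
#' For each image, neighbours are ordered by ascending Euclidean distance in
#' the latent space (self excluded; ties broken by ascending index). At each
#' rank `r` the Pearson correlation between the masked pixel vectors of the
#' image and of its rank-`r` neighbour is computed; the curve is the mean
#' over images. Using the masked pixels for every latent space avoids an
#' offset between spaces caused by the gap regions themselves.
#'
#' @param space a `latent_space`.
#' @param masked_images list of masked frames aligned with
#'   `space$image_ids`.
#' @param max_rank largest rank (must be < number of images).
#' @return Numeric vector of length `max_rank`: mean correlation per rank.
#' @export
neighbor_rank_curve <- function(space, masked_images, max_rank) {
  stopifnot(inherits(space, "latent_space"))
  n <- nrow(space$vectors)
  if (length(masked_images) != n) stop("images and latent vectors misaligned")
  if (max_rank >= n) stop("max_rank must be smaller than the number of images")
  nb <- neighbor_order(space$vectors)
  px <- lapply(masked_images, as.numeric)
  sapply(seq_len(max_rank), function(r) {
    mean(vapply(seq_len(n), function(i)
      stats::cor(px[[i]], px[[nb[[i]][r]]]), numeric(1)))
  })
}

#' k-nearest-neighbour overlap between two latent spaces
#'
#' For each image, the `k` nearest neighbours (Euclidean, self excluded,
#' ties broken by ascending index) are found in the reference space and in
#' the query space; the per-image overlap is `|intersection| / k * 100`.
#' `knn_overlap(s, s, k)` is 100 for every image.
#'
#' @param space_ref reference `latent_space` (typically the ground-truth
#'   space).
#' @param space_query query `latent_space` (masked or inpainted).
#' @param k neighbourhood size (100 is the reference value).
#' @return List with `per_image` overlap percentages, `mean` and
#'   `quartiles`.
#' @export
knn_overlap <- function(space_ref, space_query, k = 100L) {
  stopifnot(inherits(space_ref, "latent_space"),
            inherits(space_query, "latent_space"))
  if (!identical(space_ref$image_ids, space_query$image_ids))
    stop("latent spaces cover different image sets")
  n <- nrow(space_ref$vectors)
  if (k >= n) stop("k must be smaller than the number of images")
  nb_r <- neighbor_order(space_ref$vectors)
  nb_q <- neighbor_order(space_query$vectors)
  ov <- vapply(seq_len(n), function(i)
    length(intersect(nb_r[[i]][seq_len(k)], nb_q[[i]][seq_len(k)])) / k * 100,
    numeric(1))
  list(per_image = ov, mean = mean(ov),
       quartiles = stats::quantile(ov, c(0.25, 0.5, 0.75)))
}
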