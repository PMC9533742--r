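# Architecture contracts and gradient correctness. Gradient checks perturb
# biases away from zero first: with zero biases the ReLU kink sits exactly
# at the finite-difference point and the subgradient is ambiguous.

jitter_biases <- function(net, seed = 99) {
  with_seed(seed, {
    walk <- function(p) {
      if (is.list(p) && !is.null(p$b)) {
        p$b <- p$b + stats::rnorm(length(p$b), sd = 0.05)
        return(p)
      }
      if (is.list(p)) return(lapply(p, walk))
      p
    }
    net$params <- walk(net$params)
  })
  net
}

fd_gradient_check <- function(net, x, mask = NULL, paths, tol = 1e-5) {
  tgt <- with_seed(3, matrix(rnorm(length(x)), nrow(x), ncol(x)))
  loss <- function(nn) 0.5 * sum((net_forward(nn, x, mask = mask)$y - tgt)^2)
  f <- net_forward(net, x, mask = mask, want_cache = TRUE)
  g <- net_backward(net, f$cache, f$y - tgt)
  get_path <- function(p, pth) { for (k in pth) p <- p[[k]]; p }
  set_path <- function(p, pth, val) {
    if (length(pth) == 1) { p[[pth[[1]]]] <- val; return(p) }
    p[[pth[[1]]]] <- set_path(p[[pth[[1]]]], pth[-1], val)
    p
  }
  for (pth in paths) {
    w <- get_path(net$params, pth)
    ga <- get_path(g, pth)
    idx <- with_seed(7, sample(length(w), min(3, length(w))))
    for (ii in idx) {
      eps <- 1e-6
      n2 <- net
      n2$params <- set_path(net$params, pth, replace(w, ii, w[ii] + eps))
      lp <- loss(n2)
      n2$params <- set_path(net$params, pth, replace(w, ii, w[ii] - eps))
      lm <- loss(n2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(ga[ii], num, tolerance = tol,
                   label = paste(unlist(pth), collapse = "/"))
    }
  }
}

test_that("all four architectures preserve strip shape and are deterministic", {
  x <- matrix(runif(64 * 16), 64, 16)
  msk <- matrix(1, 64, 16); msk[30:32, ] <- 0
  nets <- list(build_autoencoder(2, 4, seed = 1),
               build_tunet(3, 4, 2, seed = 1),
               build_partialconv_unet(3, 4, seed = 1),
               build_msdnet(8, 3, seed = 1))
  for (net in nets) {
    m <- if (net$arch == "pconv_unet") msk else NULL
    y1 <- net_forward(net, x, mask = m)$y
    y2 <- predict(net, x, mask = m)
    expect_equal(dim(y1), dim(x))
    expect_identical(y1, y2)
  }
})

test_that("autoencoder compresses to the expected latent resolution", {
  net <- build_autoencoder(depth = 2, base_channels = 4, seed = 2)
  x <- matrix(runif(512 * 128), 512, 128)
  f <- net_forward(net, x, want_cache = TRUE)
  expect_equal(dim(f$cache$latent), c(128L, 32L, 8L))
  expect_error(net_forward(net, matrix(0, 10, 12)), "divisible")
})

test_that("tunable U-Net channel schedules follow base * growth^level", {
  expect_equal(tunet_channels(64, 2, 4), c(64L, 128L, 256L, 512L))
  expect_equal(tunet_channels(16, 2.5, 4), c(16L, 40L, 100L, 250L))
  expect_equal(tunet_channels(16, 1.5, 6), c(16L, 24L, 36L, 54L, 81L, 122L))
  net <- build_tunet(4, 16, 2.5, seed = 1)
  expect_equal(nrow(net$params$encA3$w), 100L)
  expect_error(net_forward(net, matrix(0, 12, 12)), "divisible")
})

test_that("single-patch partial convolution follows the renormalised formula", {
  w <- matrix(1 / 9, 3, 3)
  x <- matrix(1, 3, 3)
  m <- matrix(0, 3, 3); m[1, 1:3] <- 1
  out <- partial_conv(x, m, w)
  expect_equal(out$y, (3 / 9) * (9 / 3))
  expect_equal(out$m_new, 1)
  expect_equal(partial_conv(x, matrix(0, 3, 3), w), list(y = 0, m_new = 0))
  # full mask reduces to the plain convolution
  set.seed(8)
  for (i in 1:5) {
    xx <- matrix(rnorm(9), 3, 3); ww <- matrix(rnorm(9), 3, 3)
    expect_equal(partial_conv(xx, matrix(1, 3, 3), ww, b = 0.3)$y,
                 sum(ww * xx) + 0.3)
  }
  expect_error(partial_conv(x, matrix(0.5, 3, 3), w), "binary")
})

test_that("partial convolution layers equal dense convolution under a full mask", {
  set.seed(11)
  for (case in 1:100) {
    H <- sample(4:9, 1); W <- sample(4:9, 1)
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    x <- array(rnorm(H * W * cin), c(H, W, cin))
    w <- matrix(rnorm(cout * cin * 9), cout, cin * 9)
    b <- rnorm(cout)
    full <- matrix(1, H, W)
    pc <- scattergap:::pconv2d_fw(x, full, w, b, 3L, 1L)
    dense <- scattergap:::conv2d_fw(x, w, b, 3L, 1L)
    expect_equal(pc$y, dense, tolerance = 1e-12)
    expect_equal(pc$mask, full)
  }
})

test_that("the pconv U-Net mask stream only grows the valid region", {
  net <- build_partialconv_unet(3, 4, seed = 5)
  x <- matrix(runif(64 * 16), 64, 16)
  msk <- matrix(1, 64, 16)
  msk[20:24, ] <- 0; msk[, 7:8] <- 0
  f <- forward <- scattergap:::forward_pconv(net, x, msk)
  expect_true(all(f$mask_out >= msk))
  # per-layer monotonicity along the encoder
  m1 <- f$cache$enc[[1]]$fa$mask
  m2 <- f$cache$enc[[1]]$fb$mask
  expect_true(all(m1 >= msk) && all(m2 >= m1))
  # with the full mask the pconv U-Net matches a plain conv U-Net layerwise
  ones <- matrix(1, 64, 16)
  f2 <- scattergap:::forward_pconv(net, x, ones)
  expect_equal(f2$mask_out, ones)
  expect_error(net_forward(net, x), "mask")
})

test_that("dense-dilated network cycles dilations and counts parameters exactly", {
  net <- build_msdnet(200, 15, seed = 1)
  expect_equal(net$cfg$dilations[1:16], c(1:15, 1L))
  expect_equal(net$cfg$dilations[200], ((200 - 1) %% 15) + 1)

  # one layer, dilation 1: a 3x3 conv (+ReLU) and a 1x1 output conv
  n1 <- build_msdnet(1, 1, seed = 1)
  expect_equal(count_parameters(n1), 13L)

  # closed form 4.5 d^2 + 6.5 d + 2 against brute-force counting
  for (d in c(1, 2, 5, 17, 50)) {
    nd <- build_msdnet(d, 3, seed = 1)
    expect_equal(count_parameters(nd), as.integer(4.5 * d^2 + 6.5 * d + 2))
  }
  # dilation choice never changes the count
  expect_equal(count_parameters(build_msdnet(50, 12, seed = 1)),
               count_parameters(build_msdnet(50, 1, seed = 2)))
})

test_that("gradients match finite differences for every architecture", {
  x <- with_seed(21, matrix(rnorm(16 * 8), 16, 8))
  ae <- jitter_biases(build_autoencoder(2, 3, seed = 7))
  fd_gradient_check(ae, x, paths = list(list("enc1", "w"), list("enc2", "b"),
                                        list("dec2", "w"), list("up1", "w"),
                                        list("up1", "b"), list("out", "w")))
  tu <- jitter_biases(build_tunet(3, 3, 2, seed = 7))
  fd_gradient_check(tu, x, paths = list(list("encA1", "w"), list("encB3", "w"),
                                        list("up1", "w"), list("decA1", "w"),
                                        list("decB2", "b"), list("out", "w")))
  ms <- jitter_biases(build_msdnet(6, 3, seed = 7))
  fd_gradient_check(ms, x, paths = list(list("layers", 1, "w"),
                                        list("layers", 6, "w"),
                                        list("layers", 3, "b"),
                                        list("out", "w"), list("out", "b")))
  msk <- matrix(1, 16, 8); msk[6:8, 3:4] <- 0
  pc <- jitter_biases(build_partialconv_unet(3, 3, seed = 7))
  fd_gradient_check(pc, x, mask = msk,
                    paths = list(list("encA1", "w"), list("encB2", "w"),
                                 list("up2", "w"), list("decA1", "w"),
                                 list("out", "w"), list("out", "b")))
})

test_that("gradient reaches every layer of a deep dense-dilated network", {
  net <- build_msdnet(20, 5, seed = 3)
  x <- with_seed(4, matrix(rnorm(32 * 16), 32, 16))
  f <- net_forward(net, x, want_cache = TRUE)
  g <- net_backward(net, f$cache, matrix(1 / length(x), 32, 16))
  norms <- vapply(g$layers, function(l) sum(abs(l$w)), numeric(1))
  expect_true(all(norms > 0))
})

test_that("checkpoints round-trip through save and load", {
  net <- build_msdnet(4, 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".rds")
  save_net(net, path)
  net2 <- load_net(path)
  expect_identical(net2$params, net$params)
  x <- matrix(runif(16 * 8), 16, 8)
  expect_identical(predict(net, x), predict(net2, x))
})
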