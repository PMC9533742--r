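test_that("scene rendering matches the closed-form intensity model", {
  empty <- scatter_scene(center = c(16, 16), background = c(0, 1))
  expect_equal(render_scene(empty, 32, 32), matrix(0, 32, 32))

  sc <- ring_scene(radius = 20, width = 2, amplitude = 1, size = 64)
  sc$background <- c(0, 1)
  img <- render_scene(sc, 64, 64)
  # maximum attained on pixels nearest the circle of radius 20 about centre
  r <- sqrt(outer((0:63 - 32)^2, (0:63 - 32)^2, `+`))
  expect_true(abs(r[which.max(img)] - 20) <= 0.5)
  expect_equal(max(img), 1, tolerance = 1e-3)

  # direct evaluation at one pixel
  i <- 32; j <- 52  # 0-based (32, 52), radial distance 20 exactly
  expect_equal(img[i + 1, j + 1], exp(-(20 - 20)^2 / 8), tolerance = 1e-12)

  # determinism under the scene seed, with noise
  sc$noise_sigma <- 0.05
  expect_identical(render_scene(sc, 64, 64), render_scene(sc, 64, 64))

  # beamstop zeroes a central disc
  sc$beamstop <- list(shape = "disc", radius = 5)
  img2 <- render_scene(sc, 64, 64)
  expect_true(all(img2[r <= 5] == 0))
  expect_true(all(img2 >= 0))
})

test_that("scene validation rejects unphysical parameters", {
  expect_error(scatter_scene(rings = data.frame(radius = -1, width = 2,
                                                amplitude = 1)), "positive")
  expect_error(scatter_scene(rings = data.frame(radius = 10, width = 2,
                                                amplitude = 1,
                                                mod_order = 2,
                                                mod_depth = 1.5,
                                                mod_phase = 0)), "depth")
  expect_error(scatter_scene(noise_sigma = -0.1), "noise")
  expect_error(render_scene(scatter_scene(), 0, 10), "positive")
})

test_that("random scenes are reproducible and hit stress cases at the stated rates", {
  rng <- scene_ranges(size = 128,
                      h_gap_bands = matrix(c(30, 33), 1),
                      p_fourfold = 0.2)
  s1 <- with_seed(99, sample_scene(rng))
  s2 <- with_seed(99, sample_scene(rng))
  expect_identical(s1, s2)

  set.seed(123)
  n <- 1000
  hits <- sum(vapply(seq_len(n), function(i)
    "fourfold" %in% attr(sample_scene(rng), "stress"), logical(1)))
  # binomial 3 sigma around 200
  expect_true(abs(hits - 200) <= 3 * sqrt(1000 * 0.2 * 0.8))

  # a drawn gap peak lies wholly inside the configured band
  set.seed(5)
  repeat {
    sc <- sample_scene(rng)
    if ("gap_peak" %in% attr(sc, "stress")) break
  }
  pk <- sc$peaks[nrow(sc$peaks), ]
  stopifnot(nrow(sc$peaks) >= 1)
  expect_true(pk$row - 2 * pk$sigma >= 30 - 1 && pk$row + 2 * pk$sigma <= 33)

  # a fourfold quadruplet is symmetric about the centre
  set.seed(17)
  repeat {
    sc <- sample_scene(rng)
    if (identical(attr(sc, "stress"), "fourfold")) break
  }
  q <- tail(sc$peaks, 4)
  d <- sqrt((q$row - sc$center[1])^2 + (q$col - sc$center[2])^2)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
})

test_that("bicubic resampling is exact on constants and axis ramps", {
  const <- matrix(3.5, 16, 16)
  expect_equal(resize_bicubic(const, 16, 16), const)
  expect_equal(resize_bicubic(const, 7, 11), matrix(3.5, 7, 11))

  # Catmull-Rom reproduces polynomials up to degree 3 along each axis;
  # a bilinear ramp must be reproduced exactly at interior sample points
  ramp <- outer(seq_len(32), seq_len(32), function(i, j) 2 * i + 0.5 * j)
  down <- resize_bicubic(ramp, 16, 16)
  expected <- outer(seq_len(16), seq_len(16), function(i, j) {
    si <- (i - 0.5) * 2 + 0.5; sj <- (j - 0.5) * 2 + 0.5
    2 * si + 0.5 * sj
  })
  expect_equal(down[2:15, 2:15], expected[2:15, 2:15], tolerance = 1e-6)
  expect_error(resize_bicubic(matrix(0, 3, 3), 8, 8), "at least 4 x 4")
})

test_that("preprocessing is log1p followed by per-frame min-max", {
  expect_equal(preprocess_frame(matrix(2, 5, 5)), matrix(0, 5, 5))
  two <- matrix(c(0, exp(1) - 1), 1, 2)
  expect_equal(preprocess_frame(two), matrix(c(0, 1), 1, 2))
  x <- matrix(rexp(64, rate = 2), 8, 8)
  p <- preprocess_frame(x)
  expect_true(all(p >= 0 & p <= 1))
  # monotone: ordering of pixels is preserved
  expect_identical(order(p), order(x))
  expect_error(preprocess_frame(matrix(c(1, -1), 1, 2)), "negative")
  expect_error(preprocess_frame(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("mask application fills exactly the gap pixels and is idempotent", {
  m <- working_mask(64)
  x <- matrix(runif(64 * 64), 64, 64) + 1
  y <- apply_mask(x, m)
  expect_true(all(y[m$raster] == 0))
  expect_identical(y[!m$raster], x[!m$raster])
  expect_identical(apply_mask(y, m), y)
  empty <- m; empty$raster[] <- FALSE
  empty$gap_rectangles <- empty$gap_rectangles[0, ]
  expect_identical(apply_mask(x, empty), x)
  expect_error(apply_mask(matrix(0, 3, 3), m), "disagree")
})

test_that("simulated pairs have gap structure matching the acquisition setup", {
  m <- working_mask(64)
  pairs <- simulate_pairs(3, m, seed = 2)
  expect_length(pairs, 3)
  p <- pairs[[1]]
  expect_true(all(p$masked[m$raster] == 0))
  expect_identical(p$masked[!m$raster], p$truth[!m$raster])
  # truth has horizontal gaps filled by default
  hsel <- matrix(FALSE, 64, 64)
  hr <- m$gap_rectangles[m$gap_rectangles$type == "h", ]
  for (i in seq_len(nrow(hr))) hsel[(hr$row0[i] + 1):hr$row1[i], ] <- TRUE
  expect_true(any(p$truth[hsel] > 0))
  # switchable: vertical gaps stay masked in the truth
  pv <- simulate_pairs(1, m, seed = 2, truth_keeps_vgaps = TRUE)[[1]]
  vsel <- matrix(FALSE, 64, 64)
  vr <- m$gap_rectangles[m$gap_rectangles$type == "v", ]
  for (i in seq_len(nrow(vr))) vsel[, (vr$col0[i] + 1):vr$col1[i]] <- TRUE
  expect_true(all(pv$truth[vsel] == 0))
  # reproducible
  expect_identical(simulate_pairs(2, m, seed = 9)[[2]]$truth,
                   simulate_pairs(2, m, seed = 9)[[2]]$truth)
})

test_that("the native-resolution render + bicubic resize path works", {
  geom <- detector_geometry(3, 8, 487, 195, 7, 17, 1475, 1679,
                            pixel_pitch = 0.172)
  m <- working_mask(64)
  p <- simulate_pairs(1, m, seed = 3, native_geometry = geom)[[1]]
  expect_equal(dim(p$truth), c(64L, 64L))
  expect_true(all(p$truth >= 0 & p$truth <= 1))
  expect_true(all(p$masked[m$raster] == 0))
})

test_that("frames survive a 32-bit float TIFF round trip", {
  x <- matrix(runif(32 * 32), 32, 32)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_tiff(x, path)
  expect_equal(read_frame_tiff(path), x, tolerance = 1e-6)
})
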