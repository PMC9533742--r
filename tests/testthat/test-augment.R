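test_that("strip cropping yields the 7 canonical overlapping bands", {
  x <- matrix(seq_len(512 * 512), 512, 512)
  strips <- crop_strips(x)
  expect_length(strips, 7)
  expect_equal(vapply(strips, `[[`, integer(1), "offset"),
               seq(0L, 384L, by = 64L))
  for (s in strips) {
    expect_equal(dim(s$pixels), c(512L, 128L))
    expect_identical(s$pixels, x[, (s$offset + 1):(s$offset + 128)])
  }
  expect_error(crop_strips(matrix(0, 512, 256)), "square")
  # column coverage: all columns covered, interior columns by exactly 2
  cover <- integer(512)
  for (s in strips) {
    cols <- (s$offset + 1):(s$offset + 128)
    cover[cols] <- cover[cols] + 1L
  }
  expect_true(all(cover >= 1))
  expect_true(all(cover[65:448] == 2))
  expect_true(all(cover[c(1:64, 449:512)] == 1))
})

test_that("strips crossing vertical gaps are identified and discarded", {
  m0 <- working_mask(512)
  nov <- m0
  nov$gap_rectangles <- nov$gap_rectangles[nov$gap_rectangles$type == "h", ]
  expect_false(any(vapply(strip_offsets(512), has_vertical_gap, logical(1),
                          mask = nov)))
  hit <- vapply(strip_offsets(512), has_vertical_gap, logical(1), mask = m0)
  expect_equal(strip_offsets(512)[hit], c(64L, 128L, 256L, 320L))
  expect_equal(strip_offsets(512)[!hit], c(0L, 192L, 384L))
  expect_equal(sum(!hit), 3L)
})

test_that("artificial gap candidates mirror the true gap positions", {
  cfg <- artificial_gap_candidates(working_mask(512))
  expect_equal(cfg$candidates, c(-1L, 21L, 41L, 85L, 105L))
  expect_equal(cfg$gap_width, 2L)
})

test_that("artificial gap insertion fills the drawn columns only", {
  strip <- list(pixels = matrix(runif(512 * 128) + 1, 512, 128),
                offset = 0L, parent_id = 1L)
  # deterministic candidate
  ap <- insert_artificial_gap(strip, strip, candidates = -1L, gap_width = 2)
  expect_null(ap$artificial_gap)
  expect_identical(ap$input, ap$target)

  ap <- insert_artificial_gap(strip, strip, candidates = 41L, gap_width = 2)
  expect_equal(ap$artificial_gap, c(41L, 43L))
  expect_true(all(ap$input[, 42:43] == 0))
  expect_identical(ap$input[, -(42:43)], ap$target[, -(42:43)])

  expect_error(insert_artificial_gap(strip, strip, candidates = 127L,
                                     gap_width = 2), "overflow")

  # uniform draw over the candidate set
  set.seed(404)
  draws <- replicate(10000, {
    a <- insert_artificial_gap(strip, strip,
                               candidates = c(-1L, 41L, 105L), gap_width = 2)
    if (is.null(a$artificial_gap)) -1L else a$artificial_gap[1]
  })
  freq <- table(factor(draws, levels = c(-1, 41, 105)))
  sigma <- sqrt(10000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(freq - 10000 / 3) <= 3 * sigma))
})

test_that("dataset augmentation yields exactly 3 pairs per frame", {
  m <- working_mask(128)
  pairs <- simulate_pairs(2, m, seed = 21)
  aug <- augment_dataset(pairs, m, seed = 8)
  expect_length(aug, 6)
  offs <- strip_offsets(128)
  surv <- offs[!vapply(offs, has_vertical_gap, logical(1), mask = m)]
  expect_setequal(unique(vapply(aug, `[[`, integer(1), "offset")), surv)
  # input equals target away from true horizontal gaps and artificial gap
  ap <- aug[[1]]
  v <- scattergap:::pair_valid_mask(ap, m)
  expect_identical(ap$input[v == 1], ap$target[v == 1])
  expect_length(augment_dataset(list(), m, seed = 1), 0)
  # deterministic given the seed
  aug2 <- augment_dataset(pairs, m, seed = 8)
  expect_identical(aug, aug2)
  # the test-set variant applies the identical transformation at equal seed
  augt <- make_augmented_test_set(pairs, m, seed = 8)
  expect_identical(aug, augt[seq_along(aug)], ignore_attr = TRUE)
  expect_identical(attr(augt, "split"), "test")
})

test_that("streaming augmentation counts without materialising pairs", {
  m <- working_mask(128)
  base <- simulate_pairs(1, m, seed = 33)[[1]]
  res <- augment_dataset(function(i) base, m, seed = 4, n = 25,
                         collect = FALSE)
  expect_equal(res$n_pairs, 75L)
  cfg <- artificial_gap_candidates(m)
  expect_true(all(res$coords %in% cfg$candidates))
})

test_that("stitching is the exact left inverse of cropping and averages overlaps", {
  x <- matrix(rnorm(128 * 128), 128, 128)
  expect_identical(stitch_strips(crop_strips(x)), x)
  strips <- crop_strips(matrix(0, 128, 128))
  # make two overlapping strips disagree: offsets 0 and 16 share cols 17..32
  strips[[1]]$pixels[] <- 2
  strips[[2]]$pixels[] <- 6
  out <- stitch_strips(strips)
  expect_true(all(out[, 17:32] == 4))
  expect_true(all(out[, 1:16] == 2))
  const <- lapply(crop_strips(matrix(0, 128, 128)), function(s) {
    s$pixels[] <- 3.25; s
  })
  expect_true(all(stitch_strips(const) == 3.25))
  expect_error(stitch_strips(strips[-1]), "offsets")
})
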