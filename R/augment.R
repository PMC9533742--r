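# Strip cropping, vertical-gap discarding, artificial-gap insertion and
# overlap-averaged stitching. A square working frame of side S is cropped
# into 7 overlapping column bands of width S/4 with step S/8 (at the
# reference working size 512 that is 512 x 128 strips with 64 px overlap at
# offsets 0, 64, ..., 384). Strips overlapping a true vertical gap carry no
# usable ground truth there and are discarded; the survivors receive an
# artificial vertical gap at one of the local positions the true gaps occupy
# in the discarded strips, which manufactures ground truth for vertical-gap
# inpainting.

#' Strip offsets for a square working frame
#'
#' @param size frame side in pixels (multiple of 8).
#' @return Integer vector of 7 strip start columns (0-based).
#' @export
strip_offsets <- function(size = 512L) {
  size <- as.integer(size)
  if (size %% 8L != 0L) stop("working frame size must be a multiple of 8")
  seq.int(0L, 6L) * (size %/% 8L)
}

#' Crop a square frame into 7 overlapping strips
#'
#' @param image square numeric matrix of side `size`.
#' @return A list of 7 strips, each a list with `pixels` (a
#'   `size x size/4` matrix), `offset` (0-based start column) and
#'   `parent_id`.
#' @param parent_id identifier stored on every strip.
#' @export
crop_strips <- function(image, parent_id = NA_integer_) {
  if (nrow(image) != ncol(image))
    stop("strip cropping expects a square working frame")
  size <- nrow(image)
  offs <- strip_offsets(size)
  w <- size %/% 4L
  lapply(offs, function(o) {
    list(pixels = image[, (o + 1L):(o + w), drop = FALSE],
         offset = o, parent_id = parent_id)
  })
}

#' Does a strip overlap a vertical gap?
#'
#' @param strip a strip from [crop_strips()], or an integer offset.
#' @param mask `gap_mask` at the working size.
#' @param strip_width strip width in pixels (defaults to `mask$width / 4`).
#' @return `TRUE` iff any vertical-gap rectangle intersects the strip's
#'   column interval.
#' @export
has_vertical_gap <- function(strip, mask, strip_width = mask$width %/% 4L) {
  stopifnot(inherits(mask, "gap_mask"))
  offset <- if (is.list(strip)) strip$offset else as.integer(strip)
  vr <- mask$gap_rectangles[mask$gap_rectangles$type == "v", , drop = FALSE]
  if (!nrow(vr)) return(FALSE)
  any(vr$col0 < offset + strip_width & vr$col1 > offset)
}

#' Artificial-gap candidate positions
#'
#' Local start columns (plus the sentinel `-1` for "no gap") at which the
#' true vertical gaps fall inside the discarded strips; inserting artificial
#' gaps only at these positions keeps them consistent in location with the
#' true gaps the network must fill at inference time. At the reference
#' working size 512 with the PILATUS3 2M mask this is `{-1, 21, 41, 85,
#' 105}` with gap width 2.
#'
#' @param mask `gap_mask` at the working size.
#' @return List with `candidates` (integer vector including -1) and
#'   `gap_width` (pixels; the widest rescaled vertical gap).
#' @export
artificial_gap_candidates <- function(mask) {
  stopifnot(inherits(mask, "gap_mask"))
  w <- mask$width %/% 4L
  vr <- mask$gap_rectangles[mask$gap_rectangles$type == "v", , drop = FALSE]
  cand <- integer()
  for (o in strip_offsets(mask$width)) {
    if (!nrow(vr)) next
    hit <- vr$col0 < o + w & vr$col1 > o
    cand <- c(cand, vr$col0[hit] - o)
  }
  cand <- sort(unique(cand[cand >= 0L]))
  gw <- if (nrow(vr)) max(vr$col1 - vr$col0) else 1L
  cand <- cand[cand + gw <= w]
  list(candidates = c(-1L, cand), gap_width = as.integer(gw))
}

#' Insert an artificial vertical gap into a strip
#'
#' Draws one candidate start column uniformly (consuming the current RNG
#' stream); `-1` means no gap is added. The input strip gets the gap columns
#' set to `fill`; the target keeps the ground-truth values.
#'
#' @param input_strip strip whose pixels will be gapped (the network input,
#'   with the true horizontal gaps already masked).
#' @param target_strip strip holding the ground truth.
#' @param candidates integer vector of local start columns, may include -1.
#' @param gap_width artificial gap width in pixels.
#' @param fill fill value for gap pixels.
#' @return A list (`augmented_pair`) with `input`, `target`, `offset`,
#'   `parent_id` and `artificial_gap` (`c(start, end)` half-open local
#'   columns, or `NULL`).
#' @export
insert_artificial_gap <- function(input_strip, target_strip = input_strip,
                                  candidates, gap_width = 1L, fill = 0) {
  if (gap_width < 1L) stop("gap_width must be at least 1")
  w <- ncol(input_strip$pixels)
  real <- candidates[candidates >= 0L]
  if (any(real + gap_width > w))
    stop("artificial gap candidates overflow the strip width")
  c0 <- if (length(candidates) == 1L) candidates else
    candidates[sample.int(length(candidates), 1L)]
  inp <- input_strip$pixels
  gap <- NULL
  if (c0 >= 0L) {
    inp[, (c0 + 1L):(c0 + gap_width)] <- fill
    gap <- c(c0, c0 + gap_width)
  }
  structure(list(input = inp, target = target_strip$pixels,
                 offset = input_strip$offset,
                 parent_id = input_strip$parent_id,
                 artificial_gap = gap),
            class = "augmented_pair")
}

#' Build the augmented training set
#'
#' For every (masked, truth) image pair: crop into 7 strips, discard the
#' strips overlapping true vertical gaps, and insert one artificial gap draw
#' into each survivor. With the PILATUS3 2M mask 4 of 7 strips are
#' discarded, so every image contributes exactly 3 augmented pairs (4641
#' training images yield 13923).
#'
#' @param pairs list of `list(masked, truth)` square frames, or a function
#'   `f(i)` returning such a pair (streaming mode for large runs).
#' @param n number of pairs when `pairs` is a function.
#' @param mask `gap_mask` at the working size.
#' @param seed integer seed for the artificial-gap draws.
#' @param candidates,gap_width artificial-gap configuration; defaults derive
#'   from the mask via [artificial_gap_candidates()].
#' @param collect if `FALSE`, do not accumulate the augmented pairs; return
#'   only the count and the drawn gap coordinates (constant memory).
#' @return List of `augmented_pair` objects, or (when `collect = FALSE`) a
#'   list with `n_pairs` and `coords`.
#' @export
augment_dataset <- function(pairs, mask, seed = 1L, n = length(pairs),
                            candidates = NULL, gap_width = NULL,
                            collect = TRUE) {
  stopifnot(inherits(mask, "gap_mask"))
  if (is.null(candidates) || is.null(gap_width)) {
    cfg <- artificial_gap_candidates(mask)
    if (is.null(candidates)) candidates <- cfg$candidates
    if (is.null(gap_width)) gap_width <- cfg$gap_width
  }
  get_pair <- if (is.function(pairs)) pairs else function(i) pairs[[i]]
  offs <- strip_offsets(mask$width)
  survivors <- which(!vapply(offs, has_vertical_gap, logical(1), mask = mask))
  out <- if (collect) vector("list", n * length(survivors)) else NULL
  coords <- integer(n * length(survivors))
  k <- 0L
  with_seed(seed, for (i in seq_len(n)) {
    p <- get_pair(i)
    if (nrow(p$masked) != mask$height || ncol(p$masked) != mask$width)
      stop("image dimensions do not match the working mask")
    if (!identical(dim(p$masked), dim(p$truth)))
      stop("masked and truth frames are misaligned")
    in_strips <- crop_strips(p$masked, parent_id = i)
    tg_strips <- crop_strips(p$truth, parent_id = i)
    for (s in survivors) {
      ap <- insert_artificial_gap(in_strips[[s]], tg_strips[[s]],
                                  candidates, gap_width)
      k <- k + 1L
      coords[k] <- if (is.null(ap$artificial_gap)) -1L else ap$artificial_gap[1]
      if (collect) out[[k]] <- ap
    }
  })
  if (collect) out else list(n_pairs = k, coords = coords)
}

#' Augment an evaluation split
#'
#' Identical contract to [augment_dataset()], tagged as the evaluation
#' split; kept as a separate entry point so the two-track evaluation
#' protocol (horizontal gaps on stitched full images, vertical gaps on the
#' augmented test set) is explicit in calling code.
#'
#' @inheritParams augment_dataset
#' @return See [augment_dataset()]; the result carries
#'   `attr(, "split") == "test"`.
#' @export
make_augmented_test_set <- function(pairs, mask, seed = 1L,
                                    n = length(pairs), candidates = NULL,
                                    gap_width = NULL, collect = TRUE) {
  out <- augment_dataset(pairs, mask, seed = seed, n = n,
                         candidates = candidates, gap_width = gap_width,
                         collect = collect)
  attr(out, "split") <- "test"
  out
}

#' Stitch strips back into a full frame by overlap averaging
#'
#' Every output pixel is the arithmetic mean of the values of all strips
#' covering its column, which suppresses patch-edge artefacts;
#' `stitch_strips(crop_strips(x))` reproduces `x` exactly.
#'
#' @param strips list of 7 strips (as from [crop_strips()]), pixel contents
#'   possibly replaced by network output.
#' @return A square numeric matrix.
#' @export
stitch_strips <- function(strips) {
  offs <- vapply(strips, `[[`, integer(1), "offset")
  w <- ncol(strips[[1]]$pixels)
  size <- nrow(strips[[1]]$pixels)
  if (!identical(sort(offs), strip_offsets(size)))
    stop("stitching requires exactly the 7 canonical strip offsets")
  acc <- matrix(0, size, size)
  cnt <- numeric(size)
  for (s in strips) {
    cols <- (s$offset + 1L):(s$offset + w)
    acc[, cols] <- acc[, cols] + s$pixels
    cnt[cols] <- cnt[cols] + 1
  }
  sweep(acc, 2L, cnt, "/")
}
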