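#' Describe a module-tiled detector
#'
#' A tiled photon-counting detector consists of a grid of rectangular sensor
#' modules separated by dead stripes (inter-module gaps). The geometry is
#' fully determined by the module grid, the module extents and the gap
#' extents; the frame dimensions must be consistent with them:
#' `module_cols * module_width + (module_cols - 1) * v_gap_width ==
#' frame_width` and the analogous relation for rows.
#'
#' @param module_cols,module_rows number of module columns / rows.
#' @param module_width,module_height module extent in pixels.
#' @param v_gap_width width in pixels of the vertical gaps between module
#'   columns.
#' @param h_gap_height height in pixels of the horizontal gaps between module
#'   rows.
#' @param frame_width,frame_height full frame extent in pixels.
#' @param pixel_pitch physical pixel size in mm (informational only).
#' @return An object of class `detector_geometry`.
#' @seealso [pilatus3_2m()] for the PILATUS3 2M preset, [build_full_mask()].
#' @export
detector_geometry <- function(module_cols, module_rows,
                              module_width, module_height,
                              v_gap_width, h_gap_height,
                              frame_width, frame_height,
                              pixel_pitch = NA_real_) {
  g <- list(module_cols = as.integer(module_cols),
            module_rows = as.integer(module_rows),
            module_width = as.integer(module_width),
            module_height = as.integer(module_height),
            v_gap_width = as.integer(v_gap_width),
            h_gap_height = as.integer(h_gap_height),
            frame_width = as.integer(frame_width),
            frame_height = as.integer(frame_height),
            pixel_pitch = pixel_pitch)
  counts <- g[c("module_cols", "module_rows", "module_width", "module_height",
                "frame_width", "frame_height")]
  if (any(vapply(counts, function(v) is.na(v) || v <= 0L, logical(1))))
    stop("all module/frame extents must be strictly positive")
  if (g$v_gap_width < 0L || g$h_gap_height < 0L)
    stop("gap extents must be non-negative")
  w <- g$module_cols * g$module_width + (g$module_cols - 1L) * g$v_gap_width
  if (w != g$frame_width)
    stop(sprintf(paste0("inconsistent geometry: module_cols*module_width + ",
                        "(module_cols-1)*v_gap_width = %d != frame_width = %d"),
                 w, g$frame_width))
  h <- g$module_rows * g$module_height + (g$module_rows - 1L) * g$h_gap_height
  if (h != g$frame_height)
    stop(sprintf(paste0("inconsistent geometry: module_rows*module_height + ",
                        "(module_rows-1)*h_gap_height = %d != frame_height ",
                        "= %d"), h, g$frame_height))
  structure(g, class = "detector_geometry")
}

#' PILATUS3 2M detector geometry
#'
#' Three columns of eight vertically stacked modules (24 modules in total) on
#' a 1475 x 1679 pixel frame, separated by two 7-pixel-wide vertical gaps and
#' seven 17-pixel-tall horizontal gaps; pixel pitch 0.172 mm. The vertical
#' gap width is exposed as a parameter; 7 px is the value consistent with an
#' integral module width (3*487 + 2*7 = 1475).
#'
#' @param v_gap_width vertical gap width in pixels.
#' @return A [detector_geometry()] object.
#' @export
pilatus3_2m <- function(v_gap_width = 7L) {
  v_gap_width <- as.integer(v_gap_width)
  module_width <- (1475L - 2L * v_gap_width) / 3L
  if (module_width != as.integer(module_width))
    stop("v_gap_width does not yield an integral module width on 1475 px")
  detector_geometry(module_cols = 3L, module_rows = 8L,
                    module_width = as.integer(module_width),
                    module_height = 195L,
                    v_gap_width = v_gap_width, h_gap_height = 17L,
                    frame_width = 1475L, frame_height = 1679L,
                    pixel_pitch = 0.172)
}

new_gap_mask <- function(rects, height, width) {
  height <- as.integer(height); width <- as.integer(width)
  raster <- matrix(FALSE, height, width)
  if (nrow(rects)) {
    for (i in seq_len(nrow(rects))) {
      r <- rects[i, ]
      raster[(r$row0 + 1L):r$row1, (r$col0 + 1L):r$col1] <- TRUE
    }
  }
  structure(list(raster = raster, height = height, width = width,
                 gap_rectangles = rects),
            class = "gap_mask")
}

#' Build the full-resolution gap mask of a detector
#'
#' Rasterises the inter-module gaps of a tiled detector into a boolean mask
#' (`TRUE` = gap / missing pixel) together with its defining list of
#' axis-aligned rectangles. Rectangles are half-open, 0-based
#' `[row0, row1) x [col0, col1)`; horizontal gaps span the full frame width
#' and vertical gaps the full frame height.
#'
#' @param geometry a [detector_geometry()] object.
#' @return An object of class `gap_mask` with elements `raster` (logical
#'   matrix), `height`, `width` and `gap_rectangles` (data frame with columns
#'   `row0`, `row1`, `col0`, `col1`, `type`).
#' @export
build_full_mask <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  g <- geometry
  rects <- list()
  if (g$module_rows > 1L && g$h_gap_height > 0L) {
    for (k in seq_len(g$module_rows - 1L)) {
      r0 <- (k - 1L) * (g$module_height + g$h_gap_height) + g$module_height
      rects[[length(rects) + 1L]] <-
        data.frame(row0 = r0, row1 = r0 + g$h_gap_height,
                   col0 = 0L, col1 = g$frame_width, type = "h")
    }
  }
  if (g$module_cols > 1L && g$v_gap_width > 0L) {
    for (k in seq_len(g$module_cols - 1L)) {
      c0 <- (k - 1L) * (g$module_width + g$v_gap_width) + g$module_width
      rects[[length(rects) + 1L]] <-
        data.frame(row0 = 0L, row1 = g$frame_height,
                   col0 = c0, col1 = c0 + g$v_gap_width, type = "v")
    }
  }
  rects <- if (length(rects)) do.call(rbind, rects) else
    data.frame(row0 = integer(), row1 = integer(), col0 = integer(),
               col1 = integer(), type = character())
  new_gap_mask(rects, g$frame_height, g$frame_width)
}

#' Count detector modules in a gap mask
#'
#' Counts the 4-connected components of unmasked (valid) pixels; for a mask
#' built from a consistent tiled-detector geometry this equals the number of
#' modules (24 for the PILATUS3 2M).
#'
#' @param mask a `gap_mask`.
#' @return Integer component count (0 for an all-gap mask).
#' @export
count_modules <- function(mask) {
  stopifnot(inherits(mask, "gap_mask"))
  label_components4(!mask$raster)
}

#' Rescale a gap mask to a new resolution
#'
#' Scales each gap rectangle's edges by the per-axis resolution ratio,
#' rounding to the nearest integer while enforcing a minimum extent of one
#' pixel so thin gaps survive aggressive downscaling, then re-rasterises.
#' The number of rectangles is preserved and rescaling to the identical
#' resolution is the identity.
#'
#' @param mask a `gap_mask`.
#' @param out_height,out_width target resolution in pixels.
#' @return A `gap_mask` at the target resolution.
#' @export
rescale_mask <- function(mask, out_height, out_width) {
  stopifnot(inherits(mask, "gap_mask"))
  out_height <- as.integer(out_height); out_width <- as.integer(out_width)
  if (out_height <= 0L || out_width <= 0L)
    stop("output dimensions must be positive")
  sy <- out_height / mask$height
  sx <- out_width / mask$width
  rects <- mask$gap_rectangles
  if (nrow(rects)) {
    for (i in seq_len(nrow(rects))) {
      r0 <- as.integer(round(rects$row0[i] * sy))
      r1 <- as.integer(round(rects$row1[i] * sy))
      c0 <- as.integer(round(rects$col0[i] * sx))
      c1 <- as.integer(round(rects$col1[i] * sx))
      if (r1 <= r0) r1 <- min(r0 + 1L, out_height)
      if (c1 <= c0) c1 <- min(c0 + 1L, out_width)
      r0 <- min(r0, r1 - 1L); c0 <- min(c0, c1 - 1L)
      rects$row0[i] <- max(0L, r0); rects$row1[i] <- min(out_height, r1)
      rects$col0[i] <- max(0L, c0); rects$col1[i] <- min(out_width, c1)
    }
  }
  new_gap_mask(rects, out_height, out_width)
}

#' @export
print.gap_mask <- function(x, ...) {
  cat(sprintf("<gap_mask %d x %d: %d rectangles, %d gap pixels (%.2f%%)>\n",
              x$height, x$width, nrow(x$gap_rectangles), sum(x$raster),
              100 * mean(x$raster)))
  invisible(x)
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(paste0("<detector_geometry %dx%d modules of %dx%d px, ",
                     "gaps v=%d h=%d, frame %d x %d>\n"),
              x$module_cols, x$module_rows, x$module_width, x$module_height,
              x$v_gap_width, x$h_gap_height, x$frame_width, x$frame_height))
  invisible(x)
}

#' Read / write a gap mask as an 8-bit PNG
#'
#' Masks are exchanged as single-channel images with 0 = valid pixel and
#' 255 = gap. Reading reconstructs the rectangle list from maximal runs of
#' fully masked rows/columns, which is exact for masks made of full-width
#' horizontal and full-height vertical bands.
#'
#' @param mask a `gap_mask`.
#' @param path file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png` a
#'   `gap_mask`.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "gap_mask"))
  png::writePNG(ifelse(mask$raster, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  raster <- img > 0.5
  h <- nrow(raster); w <- ncol(raster)
  runs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(starts, ends)[r$values, , drop = FALSE]
  }
  hr <- runs(apply(raster, 1L, all))
  rects <- list()
  for (i in seq_len(nrow(hr)))
    rects[[length(rects) + 1L]] <- data.frame(row0 = hr[i, 1L], row1 = hr[i, 2L],
                                              col0 = 0L, col1 = w, type = "h")
  vr <- runs(apply(raster, 2L, all))
  for (i in seq_len(nrow(vr)))
    rects[[length(rects) + 1L]] <- data.frame(row0 = 0L, row1 = h,
                                              col0 = vr[i, 1L], col1 = vr[i, 2L],
                                              type = "v")
  rects <- if (length(rects)) do.call(rbind, rects) else
    data.frame(row0 = integer(), row1 = integer(), col0 = integer(),
               col1 = integer(), type = character())
  m <- new_gap_mask(rects, h, w)
  if (!identical(m$raster, raster))
    m$raster <- raster  # non-band mask: keep the raster authoritative
  m
}
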