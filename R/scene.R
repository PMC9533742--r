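# Synthetic scattering frames. Real beamline frames are not distributable, so
# a parametric generator emulates their gross structure: an isotropically
# decaying diffuse background, Debye-Scherrer rings with optional azimuthal
# modulation, localised Gaussian peaks, a beamstop shadow and Gaussian read
# noise. Intensities are non-negative; pre-processing (log + min-max) maps
# them to [0, 1] as the networks expect.

#' Evaluate code under a fixed RNG seed
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded components never perturb each other's
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parametric description of a synthetic scattering pattern
#'
#' @param center beam centre `c(row, col)` in (sub)pixels, 0-based.
#' @param rings data frame with columns `radius`, `width`, `amplitude`,
#'   `mod_order`, `mod_depth`, `mod_phase`: Gaussian annuli
#'   `A * m(theta) * exp(-(r - radius)^2 / (2 width^2))` where the azimuthal
#'   modulation `m(theta) = 1 - depth * (1 - cos(order * (theta - phase)))/2`
#'   ranges over `[1 - depth, 1]`.
#' @param peaks data frame with columns `row`, `col`, `sigma`, `amplitude`:
#'   isotropic Gaussian peaks.
#' @param background `c(amplitude, decay)`: radial power-law background
#'   `amplitude * (1 + r)^(-decay)`.
#' @param beamstop `NULL`, or a list with `shape = "disc"` and `radius`, or
#'   `shape = "rect"` and `half_width`, `half_height`; the shadow (centred on
#'   the beam centre) is set to zero intensity.
#' @param noise_sigma standard deviation of additive Gaussian read noise.
#' @param seed integer seed making the rendered noise reproducible.
#' @return An object of class `scatter_scene`.
#' @export
scatter_scene <- function(center = c(256, 256),
                          rings = NULL, peaks = NULL,
                          background = c(0, 1), beamstop = NULL,
                          noise_sigma = 0, seed = 0L) {
  empty_rings <- data.frame(radius = numeric(), width = numeric(),
                            amplitude = numeric(), mod_order = numeric(),
                            mod_depth = numeric(), mod_phase = numeric())
  empty_peaks <- data.frame(row = numeric(), col = numeric(),
                            sigma = numeric(), amplitude = numeric())
  if (is.null(rings)) rings <- empty_rings
  if (is.null(peaks)) peaks <- empty_peaks
  if (nrow(rings)) {
    for (cc in c("mod_order", "mod_depth", "mod_phase"))
      if (is.null(rings[[cc]])) rings[[cc]] <- 0
    if (any(rings$radius <= 0) || any(rings$width <= 0))
      stop("ring radii and widths must be positive")
    if (any(rings$amplitude < 0)) stop("ring amplitudes must be non-negative")
    if (any(rings$mod_depth < 0 | rings$mod_depth > 1))
      stop("azimuthal modulation depth must lie in [0, 1]")
  }
  if (nrow(peaks)) {
    if (any(peaks$sigma <= 0)) stop("peak sigmas must be positive")
    if (any(peaks$amplitude < 0)) stop("peak amplitudes must be non-negative")
  }
  if (background[1] < 0) stop("background amplitude must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(center = as.numeric(center), rings = rings, peaks = peaks,
                 background = as.numeric(background), beamstop = beamstop,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "scatter_scene")
}

#' Render a scene to an intensity frame
#'
#' Deterministic given the scene's seed. Intensity is the sum of the radial
#' background, the ring annuli and the peaks, plus Gaussian noise, clipped at
#' zero; the beamstop shadow is set to zero afterwards.
#'
#' @param scene a [scatter_scene()].
#' @param height,width output dimensions in pixels.
#' @return A numeric `height x width` matrix of non-negative intensities.
#' @export
render_scene <- function(scene, height, width) {
  stopifnot(inherits(scene, "scatter_scene"))
  height <- as.integer(height); width <- as.integer(width)
  if (height <= 0L || width <= 0L) stop("frame dimensions must be positive")
  rr <- matrix(seq_len(height) - 1, height, width) - scene$center[1]
  cc <- matrix(seq_len(width) - 1, height, width, byrow = TRUE) -
    scene$center[2]
  r <- sqrt(rr^2 + cc^2)
  img <- scene$background[1] * (1 + r)^(-scene$background[2])
  if (nrow(scene$rings)) {
    theta <- atan2(rr, cc)
    for (i in seq_len(nrow(scene$rings))) {
      g <- scene$rings[i, ]
      m <- 1 - g$mod_depth * (1 - cos(g$mod_order * (theta - g$mod_phase))) / 2
      img <- img + g$amplitude * m *
        exp(-(r - g$radius)^2 / (2 * g$width^2))
    }
  }
  if (nrow(scene$peaks)) {
    for (i in seq_len(nrow(scene$peaks))) {
      p <- scene$peaks[i, ]
      d2 <- (matrix(seq_len(height) - 1, height, width) - p$row)^2 +
        (matrix(seq_len(width) - 1, height, width, byrow = TRUE) - p$col)^2
      img <- img + p$amplitude * exp(-d2 / (2 * p$sigma^2))
    }
  }
  if (scene$noise_sigma > 0) {
    img <- img + with_seed(scene$seed,
                           matrix(stats::rnorm(height * width,
                                               sd = scene$noise_sigma),
                                  height, width))
  }
  img[img < 0] <- 0
  if (!is.null(scene$beamstop)) {
    bs <- scene$beamstop
    if (identical(bs$shape, "disc")) {
      img[r <= bs$radius] <- 0
    } else if (identical(bs$shape, "rect")) {
      img[abs(rr) <= bs$half_height & abs(cc) <= bs$half_width] <- 0
    } else stop("unknown beamstop shape")
  }
  img
}

#' Default parameter ranges for random scenes
#'
#' The ranges describe a frame family dominated by powder-like rings with
#' moderate azimuthal texture, a decaying diffuse background, occasional
#' localised peaks and a central beamstop; the three stress cases seen in
#' practice are drawn with explicit probabilities: a peak lying wholly inside
#' a horizontal gap band, a triplet of peaks tangent to the beamstop, and a
#' fourfold-symmetric peak quadruplet.
#'
#' @param size working frame size (square), used to scale radii.
#' @param h_gap_bands optional two-column matrix of half-open `[row0, row1)`
#'   horizontal gap bands at the working size, enabling the gap-peak stress
#'   case.
#' @param p_gap_peak,p_beamstop_peaks,p_fourfold stress-case probabilities.
#' @return A list of ranges consumed by [sample_scene()].
#' @export
scene_ranges <- function(size = 512L, h_gap_bands = NULL,
                         p_gap_peak = 0.15, p_beamstop_peaks = 0.15,
                         p_fourfold = 0.2) {
  list(size = as.integer(size),
       n_rings = c(1L, 4L),
       ring_radius = c(0.08, 0.45) * size,
       ring_width = c(0.004, 0.03) * size,
       ring_amplitude = c(0.3, 1),
       mod_depth = c(0, 0.8),
       mod_order = c(2L, 6L),
       n_peaks = c(0L, 3L),
       peak_sigma = c(0.004, 0.015) * size,
       peak_amplitude = c(0.3, 1),
       bg_amplitude = c(0.05, 0.6),
       bg_decay = c(0.4, 1.5),
       beamstop_radius = c(0.02, 0.06) * size,
       center_jitter = 0.04 * size,
       noise_sigma = c(0.005, 0.02),
       h_gap_bands = h_gap_bands,
       p_gap_peak = p_gap_peak,
       p_beamstop_peaks = p_beamstop_peaks,
       p_fourfold = p_fourfold)
}

runif1 <- function(lim) stats::runif(1, lim[1], lim[2])

#' Draw a random scene from parameter ranges
#'
#' Consumes the current RNG stream (seed it with `set.seed()` or wrap calls
#' in a seeded helper for reproducibility). With the configured
#' probabilities the scene includes a peak placed wholly inside a horizontal
#' gap band, peaks tangent to the beamstop, or a fourfold-symmetric peak
#' quadruplet. The drawn scene's `seed` (used for its render noise) is taken
#' from the same stream.
#'
#' @param ranges a [scene_ranges()] list.
#' @return A [scatter_scene()]. The attribute `stress` lists which stress
#'   cases were drawn.
#' @export
sample_scene <- function(ranges = scene_ranges()) {
  size <- ranges$size
  if (size <= 0L) stop("ranges must describe a positive frame size")
  ctr <- size / 2 + stats::runif(2, -1, 1) * ranges$center_jitter
  nr <- if (ranges$n_rings[2] > ranges$n_rings[1])
    sample(ranges$n_rings[1]:ranges$n_rings[2], 1) else ranges$n_rings[1]
  rings <- do.call(rbind, lapply(seq_len(nr), function(i) {
    data.frame(radius = runif1(ranges$ring_radius),
               width = runif1(ranges$ring_width),
               amplitude = runif1(ranges$ring_amplitude),
               mod_order = sample(ranges$mod_order[1]:ranges$mod_order[2], 1),
               mod_depth = runif1(ranges$mod_depth),
               mod_phase = stats::runif(1, 0, 2 * pi))
  }))
  np <- if (ranges$n_peaks[2] > ranges$n_peaks[1])
    sample(ranges$n_peaks[1]:ranges$n_peaks[2], 1) else ranges$n_peaks[1]
  peaks <- list()
  add_peak <- function(row, col, sigma, amp)
    data.frame(row = row, col = col, sigma = sigma, amplitude = amp)
  for (i in seq_len(np)) {
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- runif1(ranges$ring_radius)
    peaks[[length(peaks) + 1L]] <-
      add_peak(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang),
               runif1(ranges$peak_sigma), runif1(ranges$peak_amplitude))
  }
  stress <- character()
  bs_radius <- runif1(ranges$beamstop_radius)
  if (!is.null(ranges$h_gap_bands) && nrow(ranges$h_gap_bands) &&
      stats::runif(1) < ranges$p_gap_peak) {
    stress <- c(stress, "gap_peak")
    band <- ranges$h_gap_bands[sample(nrow(ranges$h_gap_bands), 1), ]
    # Sigma small against the band height so the peak mass stays inside it.
    sig <- max((band[2] - band[1]) / 6, 0.5)
    peaks[[length(peaks) + 1L]] <-
      add_peak(mean(band) - 0.5, stats::runif(1, 0.2, 0.8) * size, sig,
               runif1(ranges$peak_amplitude))
  }
  if (stats::runif(1) < ranges$p_beamstop_peaks) {
    stress <- c(stress, "beamstop_peaks")
    for (ang in stats::runif(1, 0, 2 * pi) + c(0, 2, 4) * pi / 3) {
      rad <- bs_radius + 1.5 * mean(ranges$peak_sigma)
      peaks[[length(peaks) + 1L]] <-
        add_peak(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang),
                 runif1(ranges$peak_sigma), runif1(ranges$peak_amplitude))
    }
  }
  if (stats::runif(1) < ranges$p_fourfold) {
    stress <- c(stress, "fourfold")
    ang <- stats::runif(1, 0, pi / 2)
    rad <- runif1(ranges$ring_radius)
    sig <- runif1(ranges$peak_sigma)
    amp <- runif1(ranges$peak_amplitude)
    for (a in ang + c(0, 0.5, 1, 1.5) * pi) {
      peaks[[length(peaks) + 1L]] <-
        add_peak(ctr[1] + rad * sin(a), ctr[2] + rad * cos(a), sig, amp)
    }
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks) else NULL
  sc <- scatter_scene(center = ctr, rings = rings, peaks = peaks,
                      background = c(runif1(ranges$bg_amplitude),
                                     runif1(ranges$bg_decay)),
                      beamstop = list(shape = "disc", radius = bs_radius),
                      noise_sigma = runif1(ranges$noise_sigma),
                      seed = sample.int(.Machine$integer.max, 1))
  attr(sc, "stress") <- stress
  sc
}

#' Bicubic frame resampling
#'
#' Separable Catmull-Rom interpolation with clamped borders; negative
#' interpolation overshoot is clipped to zero so intensities stay physical.
#'
#' @param frame numeric matrix, at least 4 x 4.
#' @param out_height,out_width target size.
#' @return Resampled matrix.
#' @export
resize_bicubic <- function(frame, out_height, out_width) {
  if (nrow(frame) < 4L || ncol(frame) < 4L)
    stop("bicubic resampling needs an input of at least 4 x 4 pixels")
  out <- bicubic_resize(frame, as.integer(out_height), as.integer(out_width))
  out[out < 0] <- 0
  out
}

#' Log-scale and normalise a frame to the unit interval
#'
#' Applies `log(1 + x)` (emphasising weak scattering while keeping zero
#' fixed) followed by per-frame min-max normalisation. A constant frame maps
#' to all zeros.
#'
#' @param frame non-negative numeric matrix.
#' @return Matrix with values in `[0, 1]`.
#' @export
preprocess_frame <- function(frame) {
  if (any(!is.finite(frame))) stop("frame contains non-finite values")
  if (any(frame < 0)) stop("frame contains negative intensities")
  v <- log1p(frame)
  rng <- range(v)
  if (rng[2] == rng[1]) return(matrix(0, nrow(frame), ncol(frame)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Apply a gap mask to a frame
#'
#' @param frame numeric matrix.
#' @param mask a `gap_mask` of matching dimensions.
#' @param fill value written into gap pixels (0 in preprocessed space).
#' @return The masked frame.
#' @export
apply_mask <- function(frame, mask, fill = 0) {
  stopifnot(inherits(mask, "gap_mask"))
  if (nrow(frame) != mask$height || ncol(frame) != mask$width)
    stop("frame and mask dimensions disagree")
  frame[mask$raster] <- fill
  frame
}

#' Generate paired (masked, ground-truth) frames
#'
#' Emulates the structure of a detector-translation dataset: the ground
#' truth has the horizontal gaps filled (it is rendered gaplessly), while
#' the vertical gaps optionally remain masked in the truth as well
#' (`truth_keeps_vgaps = TRUE`), matching data acquired by vertical detector
#' translation only. The masked frame has the full gap grid zeroed.
#'
#' Frames are rendered directly at the working size by default; with
#' `native_geometry` they are rendered at the detector's native resolution
#' and bicubically resized, exercising the full pre-processing path.
#'
#' @param n number of pairs.
#' @param mask `gap_mask` at the working size.
#' @param seed integer seed; the whole set is reproducible from it.
#' @param ranges scene parameter ranges, see [scene_ranges()].
#' @param truth_keeps_vgaps keep vertical gaps masked in the truth frames.
#' @param native_geometry optional [detector_geometry()]; if supplied, render
#'   natively then resize.
#' @return List of `n` elements, each `list(masked, truth, scene)`.
#' @export
simulate_pairs <- function(n, mask, seed = 1L, ranges = NULL,
                           truth_keeps_vgaps = FALSE,
                           native_geometry = NULL) {
  stopifnot(inherits(mask, "gap_mask"))
  size <- mask$width
  if (is.null(ranges)) {
    hb <- mask$gap_rectangles
    hb <- hb[hb$type == "h", c("row0", "row1"), drop = FALSE]
    ranges <- scene_ranges(size = size, h_gap_bands = as.matrix(hb))
  }
  vmask <- mask
  vmask$raster <- matrix(FALSE, mask$height, mask$width)
  vr <- mask$gap_rectangles[mask$gap_rectangles$type == "v", , drop = FALSE]
  if (nrow(vr))
    for (i in seq_len(nrow(vr)))
      vmask$raster[(vr$row0[i] + 1L):vr$row1[i],
                   (vr$col0[i] + 1L):vr$col1[i]] <- TRUE
  with_seed(seed, lapply(seq_len(n), function(i) {
    sc <- sample_scene(ranges)
    if (!is.null(native_geometry)) {
      sc_native <- sc
      sy <- native_geometry$frame_height / mask$height
      sx <- native_geometry$frame_width / mask$width
      sc_native$center <- sc$center * c(sy, sx)
      sc_native$rings$radius <- sc$rings$radius * (sy + sx) / 2
      sc_native$rings$width <- sc$rings$width * (sy + sx) / 2
      if (nrow(sc_native$peaks)) {
        sc_native$peaks$row <- sc$peaks$row * sy
        sc_native$peaks$col <- sc$peaks$col * sx
        sc_native$peaks$sigma <- sc$peaks$sigma * (sy + sx) / 2
      }
      if (!is.null(sc_native$beamstop) &&
          identical(sc_native$beamstop$shape, "disc"))
        sc_native$beamstop$radius <- sc$beamstop$radius * (sy + sx) / 2
      raw <- render_scene(sc_native, native_geometry$frame_height,
                          native_geometry$frame_width)
      raw <- resize_bicubic(raw, mask$height, mask$width)
    } else {
      raw <- render_scene(sc, mask$height, mask$width)
    }
    truth <- preprocess_frame(raw)
    if (truth_keeps_vgaps) truth <- apply_mask(truth, vmask)
    list(masked = apply_mask(truth, mask), truth = truth, scene = sc)
  }))
}

#' Read / write frames as 32-bit float TIFF
#'
#' @param frame numeric matrix.
#' @param path file path.
#' @return `write_frame_tiff` returns `path` invisibly; `read_frame_tiff`
#'   a numeric matrix.
#' @export
write_frame_tiff <- function(frame, path) {
  tiff::writeTIFF(frame, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_frame_tiff
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
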