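# Training recipe and gap-restricted evaluation. Networks are trained with
# plain L1 loss (no adversarial term, no extra regularisation) under ADAM
# with a step learning-rate schedule; inference on full frames crops into
# the 7 overlapping strips, runs each through the network and stitches by
# overlap averaging; evaluation restricts the metrics to gap pixels, with
# horizontal gaps scored on stitched full frames and vertical gaps on the
# augmented evaluation pairs.

#' Training configuration
#'
#' Defaults follow the common recipe for these architectures: L1 loss, ADAM
#' with default moments, initial learning rate 1e-3 dropped by a factor of
#' 10 every `lr_step` epochs (100 by default, for 300 epochs; the 200-layer
#' dense-dilated variant uses 60/180).
#'
#' @param lr_init initial learning rate.
#' @param lr_gamma multiplicative drop factor.
#' @param lr_step epochs between drops.
#' @param total_epochs epochs to train.
#' @param batch_size samples per parameter update.
#' @param seed integer seed controlling shuffling.
#' @param validation_fraction fraction of parent images held out for
#'   validation.
#' @param loss_on_gaps_only restrict the training loss to gap pixels instead
#'   of the whole target strip.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_init = 1e-3, lr_gamma = 0.1, lr_step = 100L,
                         total_epochs = 300L, batch_size = 16L, seed = 1L,
                         validation_fraction = 0.1,
                         loss_on_gaps_only = FALSE) {
  if (lr_init <= 0) stop("lr_init must be positive")
  structure(list(lr_init = lr_init, lr_gamma = lr_gamma,
                 lr_step = as.integer(lr_step),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 validation_fraction = validation_fraction,
                 loss_on_gaps_only = loss_on_gaps_only),
            class = "train_config")
}

#' Mean absolute error
#'
#' @param pred,target numeric arrays of identical shape.
#' @return Mean of `|pred - target|` over all elements.
#' @export
l1_loss <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("prediction and target shapes disagree")
  mean(abs(pred - target))
}

#' Learning rate at an epoch
#'
#' `lr_init * lr_gamma ^ floor(epoch / lr_step)` (0-based epochs).
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return The learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (any(epoch < 0) || any(epoch >= cfg$total_epochs))
    stop("epoch out of range")
  cfg$lr_init * cfg$lr_gamma^floor(epoch / cfg$lr_step)
}

# ---- ADAM -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      if (is.null(dim(p))) g <- as.numeric(g)  # vec grads arrive as n x 1
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

grad_accum <- function(acc, g, w = 1) {
  if (is.null(acc)) {
    scale <- function(p) if (is.list(p)) lapply(p, scale) else p * w
    return(scale(g))
  }
  add <- function(a, b) {
    if (is.list(a)) {
      keys <- if (is.null(names(a))) seq_along(a) else names(a)
      for (nm in keys) a[[nm]] <- add(a[[nm]], b[[nm]])
      a
    } else a + b * w
  }
  add(acc, g)
}

pair_valid_mask <- function(pair, mask) {
  # validity mask of an augmented input strip: 1 everywhere except the true
  # horizontal gap rows and the artificial gap columns
  v <- matrix(1, nrow(pair$input), ncol(pair$input))
  hr <- mask$gap_rectangles[mask$gap_rectangles$type == "h", , drop = FALSE]
  if (nrow(hr))
    for (i in seq_len(nrow(hr))) v[(hr$row0[i] + 1L):hr$row1[i], ] <- 0
  if (!is.null(pair$artificial_gap))
    v[, (pair$artificial_gap[1] + 1L):pair$artificial_gap[2]] <- 0
  v
}

#' Train an inpainting network
#'
#' Minimises the L1 loss between network output and target strips with ADAM
#' under the step learning-rate schedule of `cfg`. A fraction of parent
#' images is held out for validation (split by parent id, so strips of one
#' image never straddle the split); the returned network carries the
#' weights of the best validation epoch. Blind architectures receive the
#' input strip only; the partial-convolution network additionally receives
#' each strip's validity mask (derived from `mask` and the artificial gap).
#' Training is deterministic given `cfg$seed`.
#'
#' @param net an `inpaint_net`.
#' @param pairs list of `augmented_pair` objects.
#' @param cfg a [train_config()].
#' @param mask `gap_mask` at the working size (needed to derive validity
#'   masks and for gap-restricted losses).
#' @param verbose print per-epoch losses.
#' @return List with `net` (best-validation weights), `history` (data frame
#'   with one row per epoch: `epoch`, `train_loss`, `val_loss`, `lr`) and
#'   `best_epoch`.
#' @export
train_inpainter <- function(net, pairs, cfg, mask = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "inpaint_net"), inherits(cfg, "train_config"))
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  if (cfg$total_epochs == 0L)
    return(list(net = net, history = history, best_epoch = NA_integer_))
  if (!length(pairs)) stop("training set is empty")
  needs_mask <- net$arch == "pconv_unet"
  if ((needs_mask || cfg$loss_on_gaps_only) && is.null(mask))
    stop("this configuration requires the working-size gap mask")
  vmasks <- lapply(pairs, function(p)
    if (needs_mask || cfg$loss_on_gaps_only) pair_valid_mask(p, mask)
    else NULL)
  parent <- vapply(pairs, function(p) as.integer(p$parent_id), integer(1))
  upar <- unique(parent)
  nval <- max(0L, round(length(upar) * cfg$validation_fraction))
  val_par <- with_seed(cfg$seed + 1L,
                       if (nval > 0) sample(upar, nval) else integer())
  val_idx <- which(parent %in% val_par)
  tr_idx <- setdiff(seq_along(pairs), val_idx)
  if (!length(tr_idx)) stop("validation split left no training samples")

  sample_loss_grad <- function(idx, params, want_grad = TRUE) {
    p <- pairs[[idx]]
    net$params <- params
    f <- net_forward(net, p$input, mask = vmasks[[idx]],
                     want_cache = want_grad)
    resid <- f$y - p$target
    if (cfg$loss_on_gaps_only) {
      gap <- vmasks[[idx]] == 0
      loss <- mean(abs(resid[gap]))
      dy <- (sign(resid) * gap) / sum(gap)
    } else {
      loss <- mean(abs(resid))
      dy <- sign(resid) / length(resid)
    }
    if (!want_grad) return(list(loss = loss))
    list(loss = loss, grads = net_backward(net, f$cache, dy))
  }

  params <- net$params
  state <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = NA_integer_)
  for (epoch in seq_len(cfg$total_epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    ord <- with_seed(cfg$seed + 1000L + epoch, sample(tr_idx))
    tl <- 0
    b <- 1L
    while (b <= length(ord)) {
      bidx <- ord[b:min(b + cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in bidx) {
        r <- sample_loss_grad(i, params)
        if (!is.finite(r$loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        tl <- tl + r$loss
        acc <- grad_accum(acc, r$grads, 1 / length(bidx))
      }
      st <- adam_step(params, acc, state, lr)
      params <- st$params
      state <- st$state
      b <- b + cfg$batch_size
    }
    tl <- tl / length(ord)
    vl <- if (length(val_idx))
      mean(vapply(val_idx, function(i)
        sample_loss_grad(i, params, want_grad = FALSE)$loss, numeric(1)))
    else NA_real_
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = tl,
                                val_loss = vl, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  lr %.1e  train %.5f  val %.5f",
                      epoch, lr, tl, vl))
    score <- if (is.na(vl)) tl else vl
    if (score < best$val) best <- list(val = score, params = params,
                                       epoch = epoch)
  }
  net$params <- best$params
  list(net = net, history = history, best_epoch = best$epoch)
}

#' Inpaint a full frame with a trained network
#'
#' Crops the preprocessed masked frame into the 7 overlapping strips, runs
#' each through the network and stitches the outputs by overlap averaging.
#'
#' @param net an `inpaint_net`.
#' @param masked_image square preprocessed frame with gaps zeroed.
#' @param mask `gap_mask` at the working size (used to build the validity
#'   mask for the partial-convolution network; optional for blind models).
#' @return The stitched inpainted frame.
#' @export
infer_full_image <- function(net, masked_image, mask = NULL) {
  strips <- crop_strips(masked_image)
  needs_mask <- inherits(net, "inpaint_net") && net$arch == "pconv_unet"
  if (needs_mask) {
    if (is.null(mask)) stop("the partial-convolution network needs the mask")
    valid <- 1 - (mask$raster * 1)
  }
  out <- lapply(strips, function(s) {
    vm <- if (needs_mask)
      valid[, (s$offset + 1L):(s$offset + ncol(s$pixels)), drop = FALSE]
    else NULL
    s$pixels <- net_forward(net, s$pixels, mask = vm)$y
    s
  })
  stitch_strips(out)
}

#' Replace non-gap pixels of a prediction with the measured values
#'
#' Predicted intensities are kept only inside the gaps; everywhere else the
#' original measured pixels are restored, so inpainting never perturbs
#' trustworthy data.
#'
#' @param pred predicted frame.
#' @param input measured (masked) frame.
#' @param mask `gap_mask`.
#' @return The composited frame.
#' @export
composite_non_gap <- function(pred, input, mask) {
  stopifnot(inherits(mask, "gap_mask"))
  if (!identical(dim(pred), dim(input)) ||
      nrow(pred) != mask$height || ncol(pred) != mask$width)
    stop("shapes disagree")
  input[mask$raster] <- pred[mask$raster]
  input
}

#' Gap-restricted L1 and Pearson metrics
#'
#' Pools the gap pixels of all frames in the set and reports the mean
#' absolute error and the product-moment correlation between prediction and
#' ground truth over that pool. A zero-variance pool makes the correlation
#' undefined: it is returned as `NA` with a warning rather than silently 0.
#'
#' @param preds,truths lists of frames (or single frames).
#' @param eval_mask `gap_mask` (or logical matrix) selecting the scored
#'   pixels.
#' @return List with `l1`, `pearson` and `n_pixels`.
#' @export
gap_metrics <- function(preds, truths, eval_mask) {
  sel <- if (inherits(eval_mask, "gap_mask")) eval_mask$raster else eval_mask
  if (is.matrix(preds)) preds <- list(preds)
  if (is.matrix(truths)) truths <- list(truths)
  p <- unlist(lapply(preds, function(x) x[sel]))
  t <- unlist(lapply(truths, function(x) x[sel]))
  if (length(p) < 2L) stop("need at least 2 gap pixels")
  l1 <- mean(abs(p - t))
  if (stats::sd(t) == 0 || stats::sd(p) == 0) {
    warning("zero variance in pooled gap pixels; Pearson undefined")
    r <- NA_real_
  } else r <- stats::cor(p, t)
  list(l1 = l1, pearson = r, n_pixels = length(p))
}

#' Two-track evaluation of an inpainting method
#'
#' Horizontal gaps are scored on stitched full-frame inference against the
#' gap-filled truth; vertical gaps are scored on the augmented evaluation
#' pairs, restricted to the artificial gap columns. The report also carries
#' the mean gap-pixel intensity of the truth as context for the L1 values.
#'
#' @param method an `inpaint_net`, or the string `"biharmonic"` for the
#'   non-learned baseline.
#' @param test_pairs_full list of `list(masked, truth)` full frames.
#' @param test_pairs_aug list of `augmented_pair` objects (evaluation split).
#' @param mask `gap_mask` at the working size.
#' @return An `eval_report` list with `horizontal` and `vertical` entries
#'   (each `l1`, `pearson`, `n_pixels`, `mean_truth_intensity`) plus
#'   `per_image` L1 breakdown for the horizontal track.
#' @export
evaluate_inpainter <- function(method, test_pairs_full, test_pairs_aug,
                               mask) {
  stopifnot(inherits(mask, "gap_mask"))
  if (!length(test_pairs_full) || !length(test_pairs_aug))
    stop("evaluation sets must be non-empty")
  hsel <- matrix(FALSE, mask$height, mask$width)
  hr <- mask$gap_rectangles[mask$gap_rectangles$type == "h", , drop = FALSE]
  for (i in seq_len(nrow(hr)))
    hsel[(hr$row0[i] + 1L):hr$row1[i], ] <- TRUE
  run_full <- function(p) {
    if (identical(method, "biharmonic"))
      biharmonic_inpaint(p$masked, mask)
    else infer_full_image(method, p$masked, mask)
  }
  preds <- lapply(test_pairs_full, run_full)
  truths <- lapply(test_pairs_full, `[[`, "truth")
  hmet <- gap_metrics(preds, truths, hsel)
  per_image <- vapply(seq_along(preds), function(i)
    mean(abs(preds[[i]][hsel] - truths[[i]][hsel])), numeric(1))

  vp <- list(); vt <- list()
  for (ap in test_pairs_aug) {
    if (is.null(ap$artificial_gap)) next
    cols <- (ap$artificial_gap[1] + 1L):ap$artificial_gap[2]
    pred <- if (identical(method, "biharmonic")) {
      gm <- matrix(FALSE, nrow(ap$input), ncol(ap$input))
      gm[, cols] <- TRUE
      hrs <- mask$gap_rectangles[mask$gap_rectangles$type == "h", ,
                                 drop = FALSE]
      for (i in seq_len(nrow(hrs))) gm[(hrs$row0[i] + 1L):hrs$row1[i], ] <- TRUE
      biharmonic_inpaint(ap$input, gm)
    } else {
      vm <- if (method$arch == "pconv_unet")
        pair_valid_mask(ap, mask) else NULL
      net_forward(method, ap$input, mask = vm)$y
    }
    vp[[length(vp) + 1L]] <- pred[, cols, drop = FALSE]
    vt[[length(vt) + 1L]] <- ap$target[, cols, drop = FALSE]
  }
  vmet <- if (length(vp)) {
    pv <- unlist(vp); tv <- unlist(vt)
    list(l1 = mean(abs(pv - tv)),
         pearson = if (stats::sd(tv) > 0 && stats::sd(pv) > 0)
           stats::cor(pv, tv) else NA_real_,
         n_pixels = length(pv))
  } else list(l1 = NA_real_, pearson = NA_real_, n_pixels = 0L)

  structure(list(
    horizontal = c(hmet, list(mean_truth_intensity =
                                mean(unlist(lapply(truths, `[`, hsel))))),
    vertical = c(vmet, list(mean_truth_intensity =
                              if (length(vt)) mean(unlist(vt)) else NA_real_)),
    per_image = per_image), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("horizontal gaps: L1 = %.5f, r = %.4f (n = %d)\n",
              x$horizontal$l1, x$horizontal$pearson, x$horizontal$n_pixels))
  cat(sprintf("vertical gaps:   L1 = %.5f, r = %.4f (n = %d)\n",
              x$vertical$l1, x$vertical$pearson, x$vertical$n_pixels))
  invisible(x)
}

#' Clipped absolute difference map
#'
#' @param pred,truth frames of identical shape.
#' @param clip clip value for the absolute difference (0.15 by default, a
#'   convenient display ceiling for preprocessed intensities).
#' @return `pmin(|pred - truth|, clip)`.
#' @export
difference_map <- function(pred, truth, clip = 0.15) {
  if (!identical(dim(pred), dim(truth))) stop("shapes disagree")
  pmin(abs(pred - truth), clip)
}
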