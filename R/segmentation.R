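# Reduced mobile encoder-decoder lesion segmenter.
#
# Encoder: MobileNetV2-style inverted-residual backbone, every stage width
# scaled by the multiplier alpha (default 0.35). Decoder: atrous spatial
# pyramid (rates 6/12/18 at output stride 16) fused with a low-level
# (stride-4) feature, a 1x1 head and bilinear upsampling, closed by a
# sigmoid for binary segmentation. Trained with the soft Dice loss
# (1 - Dice), batch size 4, a 90/10 train/validation partition and Adam
# with a triangular cyclic learning rate.

width_scaled <- function(ch, alpha) max(4L, as.integer(round(ch * alpha)))

#' Segmentation model specification
#'
#' @param alpha width multiplier scaling every backbone stage, in `(0, 1]`
#'   (default 0.35).
#' @param input_size input side in pixels; must be divisible by 16 (the
#'   encoder output stride). The reference setting is 512; desk-scale runs
#'   use 64-128.
#' @param aspp_rates atrous dilation rates of the pyramid branches.
#' @return an object of class `seg_model_spec`.
#' @export
seg_model_spec <- function(alpha = 0.35, input_size = 512L,
                           aspp_rates = c(6L, 12L, 18L)) {
  if (alpha <= 0 || alpha > 1) stop("width multiplier alpha must be in (0,1]")
  if (input_size %% 16L != 0L)
    stop("input size must be divisible by the encoder output stride (16)")
  structure(list(alpha = alpha, input_size = as.integer(input_size),
                 aspp_rates = as.integer(aspp_rates)),
            class = "seg_model_spec")
}

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1L], d[2L], d[3L] + dim(b)[3L]))
  out[, , seq_len(d[3L])] <- a
  out[, , d[3L] + seq_len(dim(b)[3L])] <- b
  out
}

#' Build the lesion segmentation network
#'
#' @param spec a [seg_model_spec()].
#' @return a network module; forward maps `size x size x 3` in `[0,1]` to a
#'   `size x size x 1` probability map in `(0,1)`.
#' @export
build_segmenter <- function(spec) {
  stopifnot(inherits(spec, "seg_model_spec"))
  a <- spec$alpha
  w <- function(ch) width_scaled(ch, a)
  m <- new_module("segmenter")
  m$spec <- spec

  stem <- layer_seq(layer_conv(3L, w(32), 3L, stride = 2L, pad = 1L),
                    layer_instnorm(w(32)), layer_act("relu6"))
  b1 <- inverted_residual(w(32), w(16), stride = 1L, expand = 1L)
  b2 <- inverted_residual(w(16), w(24), stride = 2L)
  b3 <- inverted_residual(w(24), w(24), stride = 1L)   # low-level tap (OS 4)
  b4 <- inverted_residual(w(24), w(32), stride = 2L)
  b5 <- inverted_residual(w(32), w(64), stride = 2L)
  b6 <- inverted_residual(w(64), w(96), stride = 1L)   # encoder top (OS 16)

  wa <- w(64); wl <- w(24); wf <- w(64)
  aspp <- c(list(layer_seq(layer_conv(w(96), wa, 1L),
                           layer_instnorm(wa), layer_act("relu6"))),
            lapply(spec$aspp_rates, function(r)
              layer_seq(layer_conv(w(96), wa, 3L, pad = r, dilation = r),
                        layer_instnorm(wa), layer_act("relu6"))))
  aspp_proj <- layer_seq(layer_conv(length(aspp) * wa, wa, 1L),
                         layer_instnorm(wa), layer_act("relu6"))
  low_proj <- layer_seq(layer_conv(w(24), wl, 1L),
                        layer_instnorm(wl), layer_act("relu6"))
  up_mid <- layer_upsample(4L)
  fuse <- layer_seq(layer_conv(wa + wl, wf, 3L, pad = 1L),
                    layer_instnorm(wf), layer_act("relu6"))
  head <- layer_conv(wf, 1L, 1L)
  up_out <- layer_upsample(4L)
  out_act <- layer_act("sigmoid")

  m$children <- c(list(stem, b1, b2, b3, b4, b5, b6), aspp,
                  list(aspp_proj, low_proj, up_mid, fuse, head, up_out,
                       out_act))
  m$widths <- c(stem = w(32), b1 = w(16), b2 = w(24), b4 = w(32),
                b5 = w(64), b6 = w(96), aspp = wa, low = wl, fuse = wf)

  m$forward <- function(x) {
    d <- dim(x)
    stopifnot(length(d) == 3L, d[3L] == 3L, d[1L] %% 16L == 0L,
              d[1L] == d[2L])
    h <- stem$forward(x)
    h <- b1$forward(h)
    h <- b2$forward(h)
    low <- b3$forward(h)
    h <- b4$forward(low)
    h <- b5$forward(h)
    top <- b6$forward(h)
    branches <- lapply(aspp, function(br) br$forward(top))
    A <- Reduce(concat_ch, branches)
    ap <- aspp_proj$forward(A)
    apu <- up_mid$forward(ap)
    L <- low_proj$forward(low)
    fused <- fuse$forward(concat_ch(apu, L))
    logit <- up_out$forward(head$forward(fused))
    m$cache <- list(wa = dim(ap)[3L], n_branch = length(branches),
                    bw = dim(branches[[1L]])[3L])
    out_act$forward(logit)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d_logit <- out_act$backward(dy)
    d_fused <- fuse$backward(head$backward(up_out$backward(d_logit)))
    wa_ch <- cc$wa
    d_apu <- d_fused[, , seq_len(wa_ch), drop = FALSE]
    d_L <- d_fused[, , -seq_len(wa_ch), drop = FALSE]
    d_low1 <- low_proj$backward(d_L)
    d_A <- aspp_proj$backward(up_mid$backward(d_apu))
    d_top <- 0
    for (i in seq_along(aspp)) {
      sel <- (i - 1L) * cc$bw + seq_len(cc$bw)
      d_top <- d_top + aspp[[i]]$backward(d_A[, , sel, drop = FALSE])
    }
    d_low2 <- b4$backward(b5$backward(b6$backward(d_top)))
    d_h <- b3$backward(d_low1 + d_low2)
    stem$backward(b1$backward(b2$backward(d_h)))
  }
  m
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)`,
#' bounded in `[0, 1]`.
#'
#' @param pred probability map.
#' @param truth binary mask of the same shape.
#' @param smooth smoothing constant protecting the empty-mask case.
#' @return scalar loss.
#' @export
soft_dice_loss <- function(pred, truth, smooth = 1) {
  stopifnot(length(pred) == length(truth))
  p <- as.vector(pred); t <- as.vector(truth)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

soft_dice_grad <- function(pred, truth, smooth = 1) {
  p <- as.vector(pred); t <- as.vector(truth)
  denom <- sum(p) + sum(t) + smooth
  num <- 2 * sum(p * t) + smooth
  -(2 * t * denom - num) / denom^2
}

# rotation about the gray axis: a cheap, invertible hue shift
hue_rotation_matrix <- function(angle) {
  u <- rep(1 / sqrt(3), 3)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Classic augmentation for segmentation training
#'
#' Geometric operations (horizontal/vertical flip, transpose) are applied
#' identically to image and mask; photometric operations (brightness,
#' contrast, saturation, hue, Gaussian noise) touch the image only, so the
#' mask stays binary. All draws are deterministic in `rng_seed`.
#'
#' @param image `H x W x 3` array in `[0,1]` (square).
#' @param mask binary `H x W` matrix.
#' @param rng_seed integer seed.
#' @return `list(image, mask, ops)` where `ops` records the geometric
#'   transforms applied (for equivariance bookkeeping).
#' @export
augment <- function(image, mask, rng_seed) {
  d <- dim(image)
  stopifnot(all(dim(mask) == d[1:2]), d[1L] == d[2L])
  if (!all(mask %in% c(0, 1))) stop("augment() requires a binary mask")
  with_seed(rng_seed, {
    ops <- list(hflip = stats::runif(1) < 0.5,
                vflip = stats::runif(1) < 0.5,
                transpose = stats::runif(1) < 0.5)
    if (ops$hflip) {
      image <- image[, rev(seq_len(d[2L])), , drop = FALSE]
      mask <- mask[, rev(seq_len(d[2L])), drop = FALSE]
    }
    if (ops$vflip) {
      image <- image[rev(seq_len(d[1L])), , , drop = FALSE]
      mask <- mask[rev(seq_len(d[1L])), , drop = FALSE]
    }
    if (ops$transpose) {
      image <- aperm(image, c(2L, 1L, 3L))
      mask <- t(mask)
    }
    # photometric: image only
    image <- image + stats::runif(1, -0.12, 0.12)                # brightness
    image <- (image - 0.5) * stats::runif(1, 0.85, 1.15) + 0.5   # contrast
    lum <- luminance(clamp(image, 0, 1))
    sat <- stats::runif(1, 0.85, 1.15)
    for (c in 1:3) image[, , c] <- lum + sat * (image[, , c] - lum)
    R <- hue_rotation_matrix(stats::runif(1, -0.1, 0.1))
    flat <- matrix(image, d[1L] * d[2L], 3L) %*% t(R)
    image <- array(flat, d)
    if (stats::runif(1) < 0.5)
      image <- image + stats::rnorm(length(image), 0,
                                    stats::runif(1, 0, 0.03))
    list(image = clamp(image, 0, 1), mask = mask, ops = ops)
  })
}

#' Segmentation training configuration
#'
#' @param spec a [seg_model_spec()].
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 4).
#' @param lr_bounds lower/upper bounds of the triangular cyclic learning
#'   rate (defaults 1e-4 and 3e-3, chosen so desk-scale training converges
#'   within tens of epochs).
#' @param lr_step_epochs half-cycle length in epochs (default 4).
#' @param val_fraction validation share of the internal split (default 0.1,
#'   i.e. a 90/10 partition).
#' @param threshold binarisation threshold for validation Dice.
#' @param smooth soft-Dice smoothing constant.
#' @param augment_data apply classic augmentation to training samples.
#' @param seed root seed.
#' @param verbose print per-epoch metrics.
#' @return an object of class `seg_train_config`.
#' @export
seg_train_config <- function(spec = seg_model_spec(), epochs = 20L,
                             batch_size = 4L, lr_bounds = c(1e-4, 3e-3),
                             lr_step_epochs = 4L, val_fraction = 0.1,
                             threshold = 0.5, smooth = 1,
                             augment_data = TRUE, seed = 1L,
                             verbose = FALSE) {
  stopifnot(inherits(spec, "seg_model_spec"), epochs >= 1, batch_size >= 1,
            length(lr_bounds) == 2, lr_bounds[1] > 0,
            lr_bounds[2] >= lr_bounds[1], val_fraction > 0, val_fraction < 1)
  structure(list(spec = spec, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_bounds = lr_bounds,
                 lr_step_epochs = as.integer(lr_step_epochs),
                 val_fraction = val_fraction, threshold = threshold,
                 smooth = smooth, augment_data = isTRUE(augment_data),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "seg_train_config")
}

triangular_lr <- function(it, step_size, lo, hi) {
  cycle <- floor(1 + it / (2 * step_size))
  xpos <- abs(it / step_size - 2 * cycle + 1)
  lo + (hi - lo) * max(0, 1 - xpos)
}

hard_dice <- function(pred_mask, truth) {
  inter <- sum(pred_mask * truth)
  denom <- sum(pred_mask) + sum(truth)
  if (denom == 0) return(1)
  2 * inter / denom
}

#' Train the lesion segmenter
#'
#' Honors an internal 90/10 train/validation partition (configurable), logs
#' per-epoch training loss, validation Dice and the cyclic learning rate,
#' and returns the checkpoint with the best validation Dice.
#'
#' @param dataset a `d2m_dataset`; every sample must carry a mask and an
#'   image in `[0,1]` at the configured input size.
#' @param config a [seg_train_config()].
#' @return an object of class `segmenter_fit` with elements `model`,
#'   `history`, `lr_log`, `best_epoch`, `best_val_dice`.
#' @export
train_segmenter <- function(dataset, config) {
  stopifnot(inherits(config, "seg_train_config"))
  if (length(dataset) == 0) stop("dataset is empty")
  size <- config$spec$input_size
  for (s in dataset) {
    if (is.null(s$mask)) stop("sample ", s$id, " has no mask")
    d <- dim(s$image)
    if (d[1L] != size || d[2L] != size)
      stop("images must be ", size, "x", size)
    if (min(s$image) < -1e-9 || max(s$image) > 1 + 1e-9)
      stop("segmentation images must be in [0,1]")
  }
  split <- split_dataset(dataset, c(train = 1 - config$val_fraction,
                                    val = config$val_fraction),
                         seed = derive_seed(config$seed, "seg-split"))
  train <- dataset_subset(split, "train")
  val <- dataset_subset(split, "val")
  if (length(train) == 0 || length(val) == 0)
    stop("train/validation split produced an empty subset")

  model <- with_seed(derive_seed(config$seed, "seg-init"),
                     build_segmenter(config$spec))
  opt <- make_adam(model, lr = config$lr_bounds[1], beta1 = 0.9)
  iters_per_epoch <- ceiling(length(train) / config$batch_size)
  step_size <- config$lr_step_epochs * iters_per_epoch
  it <- 0L
  lr_log <- numeric(0)
  hist <- vector("list", config$epochs)
  best <- list(dice = -Inf, epoch = NA_integer_, state = NULL)

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("seg-epoch-", epoch)),
                     sample(length(train)))
    ep_loss <- 0
    for (bi in seq_len(iters_per_epoch)) {
      idx <- ord[((bi - 1L) * config$batch_size + 1L):
                   min(bi * config$batch_size, length(train))]
      idx <- idx[!is.na(idx)]
      zero_grads(model)
      batch_loss <- 0
      for (k in seq_along(idx)) {
        s <- train[[idx[k]]]
        if (config$augment_data) {
          aug <- augment(s$image, s$mask,
                         derive_seed(config$seed,
                                     paste0("aug-", epoch, "-", s$id)))
          img <- aug$image; msk <- aug$mask
        } else {
          img <- s$image; msk <- s$mask
        }
        pred <- model$forward(img)
        loss <- soft_dice_loss(pred, msk, config$smooth)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, " (sample ", s$id, ")")
        batch_loss <- batch_loss + loss
        g <- soft_dice_grad(pred, msk, config$smooth) / length(idx)
        model$backward(array(g, dim(pred)))
      }
      opt$lr <- triangular_lr(it, step_size, config$lr_bounds[1],
                              config$lr_bounds[2])
      lr_log <- c(lr_log, opt$lr)
      adam_step(opt)
      it <- it + 1L
      ep_loss <- ep_loss + batch_loss / length(idx)
    }
    val_dice <- mean(vapply(val, function(s) {
      hard_dice(predict_mask(model, s$image, config$threshold), s$mask)
    }, 0))
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / iters_per_epoch,
                                val_dice = val_dice)
    if (val_dice > best$dice)
      best <- list(dice = val_dice, epoch = epoch, state = get_state(model))
    if (config$verbose)
      message(sprintf("epoch %3d  loss %.4f  val dice %.4f", epoch,
                      ep_loss / iters_per_epoch, val_dice))
  }
  set_state(model, best$state)
  structure(list(model = model, history = do.call(rbind, hist),
                 lr_log = lr_log, best_epoch = best$epoch,
                 best_val_dice = best$dice, config = config),
            class = "segmenter_fit")
}

#' Predict a binary lesion mask
#'
#' @param model a segmenter network or a `segmenter_fit`.
#' @param image `H x W x 3` array in `[0,1]`.
#' @param threshold probability cut; foreground where `p >= threshold`.
#' @return binary `H x W` integer matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (inherits(model, "segmenter_fit")) model <- model$model
  prob <- model$forward(image)
  (matrix(prob, dim(image)[1L], dim(image)[2L]) >= threshold) * 1L
}
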