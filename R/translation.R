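# Unpaired two-domain adversarial translator.
#
# Domain binding (fixed throughout the package): X = dermoscopic,
# Y = macroscopic, G : X -> Y produces TransMacro images, F : Y -> X produces
# TransDermo images, with patch discriminators D_X and D_Y on each domain.
# The full objective is
#   L(G, F, D_X, D_Y) = L_GAN(F, D_X) + L_GAN(G, D_Y) + lambda * L_cyc(G, F)
# with lambda = 10 by default; generators are trained against sigmoid
# cross-entropy of their discriminator's patch map versus an array of ones,
# discriminators against real-vs-ones plus pooled-fake-vs-zeros, halved.

#' Generator architecture specification
#'
#' Encoder (7x7 stride-1 conv, then two 3x3 stride-2 convs, each with
#' instance norm + ReLU and reflection padding before the 7x7), a transformer
#' of `n_residual_blocks` residual blocks (default 12), and a decoder of two
#' 3x3 stride-2 transposed convolutions plus a 7x7 output conv with tanh.
#'
#' @param input_size input side in pixels; must be divisible by 4 (two
#'   stride-2 stages).
#' @param base_channels channel width of the first stage.
#' @param n_residual_blocks number of transformer residual blocks (>= 1).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(input_size = 64L, base_channels = 32L,
                           n_residual_blocks = 12L) {
  if (input_size %% 4L != 0L)
    stop("generator input size must be divisible by 4")
  stopifnot(n_residual_blocks >= 1, base_channels >= 1)
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 n_residual_blocks = as.integer(n_residual_blocks)),
            class = "generator_spec")
}

#' PatchGAN discriminator specification
#'
#' Five 4x4 stride-2 convolutions with instance norm and leaky ReLU between
#' layers; the last layer maps to a one-channel sigmoid patch map, each entry
#' judging one receptive-field patch of the input.
#'
#' @param input_size input side in pixels; must be at least `2^n_layers`.
#' @param base_channels width of the first conv layer.
#' @param n_layers number of conv layers (default 5).
#' @return an object of class `discriminator_spec`.
#' @export
discriminator_spec <- function(input_size = 64L, base_channels = 32L,
                               n_layers = 5L) {
  stopifnot(n_layers >= 2, base_channels >= 1)
  if (input_size < 2^n_layers)
    stop("discriminator input ", input_size, " smaller than receptive ",
         "field of ", n_layers, " stride-2 layers")
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 n_layers = as.integer(n_layers)),
            class = "discriminator_spec")
}

#' Build a translation generator network
#'
#' @param spec a [generator_spec()].
#' @param init_sd Gaussian weight-init standard deviation (mean 0).
#' @return a network module; forward maps `size x size x 3` in `[-1,1]` to
#'   the same shape and range.
#' @export
build_generator <- function(spec, init_sd = 0.02) {
  stopifnot(inherits(spec, "generator_spec"))
  b <- spec$base_channels
  res <- lapply(seq_len(spec$n_residual_blocks),
                function(i) residual_block(4L * b, init_sd = init_sd))
  net <- do.call(layer_seq, c(
    list(layer_pad_reflect(3L),
         layer_conv(3L, b, 7L, init_sd = init_sd), layer_instnorm(b),
         layer_act("relu"),
         layer_conv(b, 2L * b, 3L, stride = 2L, pad = 1L, init_sd = init_sd),
         layer_instnorm(2L * b), layer_act("relu"),
         layer_conv(2L * b, 4L * b, 3L, stride = 2L, pad = 1L,
                    init_sd = init_sd),
         layer_instnorm(4L * b), layer_act("relu")),
    res,
    list(layer_conv_transpose(4L * b, 2L * b, 3L, stride = 2L, pad = 1L,
                              init_sd = init_sd),
         layer_instnorm(2L * b), layer_act("relu"),
         layer_conv_transpose(2L * b, b, 3L, stride = 2L, pad = 1L,
                              init_sd = init_sd),
         layer_instnorm(b), layer_act("relu"),
         layer_pad_reflect(3L),
         layer_conv(b, 3L, 7L, init_sd = init_sd),
         layer_act("tanh"))))
  net$type <- "generator"
  net$spec <- spec
  net
}

#' Number of residual blocks in a network
#' @param net a network module.
#' @return integer count of residual transformer blocks.
#' @export
count_residual_blocks <- function(net) {
  sum(vapply(collect_modules(net), function(m) m$type == "residual", TRUE))
}

#' Build a PatchGAN discriminator network
#'
#' @param spec a [discriminator_spec()].
#' @param init_sd Gaussian weight-init standard deviation.
#' @return a network module; forward maps `size x size x 3` to a
#'   `(size / 2^n_layers)` patch map of probabilities in `(0,1)`.
#' @export
build_discriminator <- function(spec, init_sd = 0.02) {
  stopifnot(inherits(spec, "discriminator_spec"))
  b <- spec$base_channels
  layers <- list(layer_conv(3L, b, 4L, stride = 2L, pad = 1L,
                            init_sd = init_sd),
                 layer_act("lrelu"))
  ch <- b
  for (i in 2:(spec$n_layers - 1L)) {
    nxt <- min(8L * b, 2L * ch)
    layers <- c(layers, list(
      layer_conv(ch, nxt, 4L, stride = 2L, pad = 1L, init_sd = init_sd),
      layer_instnorm(nxt), layer_act("lrelu")))
    ch <- nxt
  }
  layers <- c(layers, list(
    layer_conv(ch, 1L, 4L, stride = 2L, pad = 1L, init_sd = init_sd),
    layer_act("sigmoid")))
  net <- do.call(layer_seq, layers)
  net$type <- "discriminator"
  net$spec <- spec
  net
}

bce_clip <- function(p) clamp(p, 1e-7, 1 - 1e-7)

#' Adversarial (sigmoid cross-entropy) loss of a patch map
#'
#' Mean binary cross-entropy of discriminator patch probabilities against a
#' constant target of ones (generator objective / real images) or zeros
#' (fake images).
#'
#' @param patch_probs array of probabilities strictly in `(0,1)`.
#' @param target `"ones"` or `"zeros"`.
#' @return nonnegative scalar.
#' @export
adversarial_loss <- function(patch_probs, target = c("ones", "zeros")) {
  target <- match.arg(target)
  if (any(patch_probs <= 0) || any(patch_probs >= 1))
    stop("patch probabilities must lie strictly in (0,1)")
  if (target == "ones") mean(-log(patch_probs)) else mean(-log(1 - patch_probs))
}

# loss and dL/dp in one pass (training path; clipped for stability)
adv_loss_grad <- function(p, real_target) {
  pc <- bce_clip(p)
  n <- length(p)
  if (real_target)
    list(loss = mean(-log(pc)), grad = array(-1 / (pc * n), dim(p)))
  else
    list(loss = mean(-log(1 - pc)), grad = array(1 / ((1 - pc) * n), dim(p)))
}

#' Cycle-consistency loss
#'
#' Mean absolute reconstruction error of both translation directions,
#' summed: an image translated to the other domain and back should be
#' comparable to the original.
#'
#' @param x_batch,x_reconstructed dermoscopic originals and their
#'   back-translations `F(G(x))`.
#' @param y_batch,y_reconstructed macroscopic originals and `G(F(y))`.
#' @return nonnegative scalar.
#' @export
cycle_loss <- function(x_batch, x_reconstructed, y_batch, y_reconstructed) {
  mean(abs(x_batch - x_reconstructed)) + mean(abs(y_batch - y_reconstructed))
}

#' Full translation objective
#'
#' @param L_gan_F,L_gan_G adversarial losses of the two mapping directions.
#' @param L_cyc cycle-consistency loss.
#' @param lambda_cyc cycle weight (default 10).
#' @return `L_gan_F + L_gan_G + lambda_cyc * L_cyc`.
#' @export
total_loss <- function(L_gan_F, L_gan_G, L_cyc, lambda_cyc = 10) {
  L_gan_F + L_gan_G + lambda_cyc * L_cyc
}

#' Translator training configuration
#'
#' @param gen_spec a [generator_spec()].
#' @param disc_spec a [discriminator_spec()]; must share `input_size`.
#' @param lambda_cyc cycle-consistency weight (default 10).
#' @param identity_loss_weight optional identity-mapping L1 term weight;
#'   0 disables it (the default).
#' @param learning_rate Adam learning rate (default 2e-4, beta1 = 0.5).
#' @param init_sd Gaussian weight initialisation sd (mean 0, default 0.02).
#' @param max_epochs epoch cap (the reference protocol caps at 1000; smoke
#'   runs use far fewer).
#' @param image_pool_size discriminator history pool size (default 50).
#' @param early_stop_window,early_stop_tol stop when the relative spread of
#'   the generator loss over the last `early_stop_window` epochs falls below
#'   `early_stop_tol` (a programmatic stand-in for loss-stabilisation
#'   stopping).
#' @param seed root seed for initialisation, shuffling and the image pool.
#' @param verbose print per-epoch losses.
#' @return an object of class `cyclegan_config`.
#' @export
cyclegan_config <- function(gen_spec = generator_spec(),
                            disc_spec = discriminator_spec(),
                            lambda_cyc = 10, identity_loss_weight = 0,
                            learning_rate = 2e-4, init_sd = 0.02,
                            max_epochs = 30L, image_pool_size = 50L,
                            early_stop_window = 10L, early_stop_tol = 0.02,
                            seed = 1L, verbose = FALSE) {
  stopifnot(lambda_cyc > 0, learning_rate > 0, identity_loss_weight >= 0,
            max_epochs >= 1, image_pool_size >= 1,
            gen_spec$input_size == disc_spec$input_size)
  structure(list(gen_spec = gen_spec, disc_spec = disc_spec,
                 lambda_cyc = lambda_cyc,
                 identity_loss_weight = identity_loss_weight,
                 learning_rate = learning_rate, init_sd = init_sd,
                 max_epochs = as.integer(max_epochs),
                 image_pool_size = as.integer(image_pool_size),
                 early_stop_window = as.integer(early_stop_window),
                 early_stop_tol = early_stop_tol,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "cyclegan_config")
}

# history image pool: returns an image for the discriminator, sometimes
# swapping in a stored past fake (stabilises discriminator training)
pool_query <- function(pool, img) {
  if (length(pool$items) < pool$size) {
    pool$items[[length(pool$items) + 1L]] <- img
    return(img)
  }
  if (stats::runif(1) < 0.5) return(img)
  j <- sample.int(length(pool$items), 1L)
  out <- pool$items[[j]]
  pool$items[[j]] <- img
  out
}

new_pool <- function(size) {
  p <- new.env(parent = emptyenv())
  p$items <- list()
  p$size <- size
  p
}

check_gan_range <- function(ds, size, name) {
  for (s in ds) {
    d <- dim(s$image)
    if (d[1L] != size || d[2L] != size)
      stop(name, " images must be ", size, "x", size, " (got ",
           d[1L], "x", d[2L], ")")
    if (min(s$image) < -1 - 1e-9 || max(s$image) > 1 + 1e-9)
      stop(name, " images must be in [-1,1]; use resize_and_scale(..., ",
           "value_range = \"sym\")")
  }
}

#' Train the two-domain translator
#'
#' Batch-size-1 alternating optimisation: generators G (dermo to macro) and
#' F (macro to dermo) are updated jointly on adversarial + cycle (+ optional
#' identity) losses, then each discriminator on real-vs-ones and
#' pooled-fake-vs-zeros cross-entropy, halved. Deterministic under the
#' configuration seed.
#'
#' @param dermo,macro `d2m_dataset`s of samples with images in `[-1,1]` at
#'   the configured input size.
#' @param config a [cyclegan_config()].
#' @return a `translation_bundle`: networks `G`, `F`, `D_X`, `D_Y` plus a
#'   per-epoch `history` data frame.
#' @export
train_cyclegan <- function(dermo, macro, config) {
  stopifnot(inherits(config, "cyclegan_config"))
  if (length(dermo) == 0 || length(macro) == 0)
    stop("both domain datasets must be nonempty")
  size <- config$gen_spec$input_size
  check_gan_range(dermo, size, "dermo")
  check_gan_range(macro, size, "macro")

  nets <- with_seed(derive_seed(config$seed, "cyclegan-init"), {
    list(G = build_generator(config$gen_spec, config$init_sd),
         F = build_generator(config$gen_spec, config$init_sd),
         D_X = build_discriminator(config$disc_spec, config$init_sd),
         D_Y = build_discriminator(config$disc_spec, config$init_sd))
  })
  G <- nets$G; F_ <- nets$F; D_X <- nets$D_X; D_Y <- nets$D_Y
  opt_G <- make_adam(list(G, F_), lr = config$learning_rate, beta1 = 0.5)
  opt_D <- make_adam(list(D_X, D_Y), lr = config$learning_rate, beta1 = 0.5)
  pool_x <- new_pool(config$image_pool_size)
  pool_y <- new_pool(config$image_pool_size)
  lam <- config$lambda_cyc
  idw <- config$identity_loss_weight

  hist <- vector("list", config$max_epochs)
  n_x <- length(dermo); n_y <- length(macro)
  steps <- max(n_x, n_y)

  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, paste0("cyclegan-epoch-", epoch)))
    ix <- sample(rep_len(sample(n_x), steps))
    iy <- sample(rep_len(sample(n_y), steps))
    acc <- c(gan_G = 0, gan_F = 0, cyc = 0, idt = 0, D_X = 0, D_Y = 0)

    for (s in seq_len(steps)) {
      x <- dermo[[ix[s]]]$image
      y <- macro[[iy[s]]]$image
      npix <- length(x)

      # ---- generator phase: joint update of G and F ----
      zero_grads(G); zero_grads(F_)
      l_idt <- 0
      if (idw > 0) {
        # identity-mapping term: feeding a target-domain image through the
        # generator should change little
        y_id <- G$forward(y)
        G$backward(idw * sign(y_id - y) / npix)
        x_id <- F_$forward(x)
        F_$backward(idw * sign(x_id - x) / npix)
        l_idt <- idw * (mean(abs(y_id - y)) + mean(abs(x_id - x)))
      }
      y_fake <- G$forward(x)
      ag <- adv_loss_grad(D_Y$forward(y_fake), real_target = TRUE)
      d_yf <- D_Y$backward(ag$grad)          # grads into D_Y discarded later
      x_rec <- F_$forward(y_fake)
      l_cyc_fwd <- mean(abs(x_rec - x))
      d_yf <- d_yf + F_$backward(lam * sign(x_rec - x) / npix)
      G$backward(d_yf)

      x_fake <- F_$forward(y)
      af <- adv_loss_grad(D_X$forward(x_fake), real_target = TRUE)
      d_xf <- D_X$backward(af$grad)
      y_rec <- G$forward(x_fake)
      l_cyc_bwd <- mean(abs(y_rec - y))
      d_xf <- d_xf + G$backward(lam * sign(y_rec - y) / npix)
      F_$backward(d_xf)
      adam_step(opt_G)

      # ---- discriminator phase (fakes detached, history pool) ----
      zero_grads(D_X); zero_grads(D_Y)
      y_pool <- pool_query(pool_y, y_fake)
      x_pool <- pool_query(pool_x, x_fake)
      r <- adv_loss_grad(D_Y$forward(y), real_target = TRUE)
      D_Y$backward(0.5 * r$grad)
      f <- adv_loss_grad(D_Y$forward(y_pool), real_target = FALSE)
      D_Y$backward(0.5 * f$grad)
      l_dy <- 0.5 * (r$loss + f$loss)
      r <- adv_loss_grad(D_X$forward(x), real_target = TRUE)
      D_X$backward(0.5 * r$grad)
      f <- adv_loss_grad(D_X$forward(x_pool), real_target = FALSE)
      D_X$backward(0.5 * f$grad)
      l_dx <- 0.5 * (r$loss + f$loss)
      adam_step(opt_D)

      step_losses <- c(ag$loss, af$loss, l_cyc_fwd + l_cyc_bwd, l_idt,
                       l_dx, l_dy)
      if (any(!is.finite(step_losses)))
        stop("non-finite loss at epoch ", epoch, " step ", s, ": ",
             paste(signif(step_losses, 4), collapse = ", "))
      acc <- acc + step_losses
    }

    acc <- acc / steps
    gen_total <- total_loss(acc[["gan_F"]], acc[["gan_G"]], acc[["cyc"]],
                            lam) + acc[["idt"]]
    hist[[epoch]] <- data.frame(
      epoch = epoch, loss_gen_total = gen_total,
      loss_gan_G = acc[["gan_G"]], loss_gan_F = acc[["gan_F"]],
      loss_cyc = acc[["cyc"]], loss_idt = acc[["idt"]],
      loss_D_X = acc[["D_X"]], loss_D_Y = acc[["D_Y"]])
    if (config$verbose)
      message(sprintf("epoch %3d  gen %.4f  cyc %.4f  D_X %.4f  D_Y %.4f",
                      epoch, gen_total, acc[["cyc"]], acc[["D_X"]],
                      acc[["D_Y"]]))
    # early stop on generator-loss stabilisation
    w <- config$early_stop_window
    if (epoch >= w) {
      recent <- vapply(hist[(epoch - w + 1L):epoch],
                       function(h) h$loss_gen_total, 0)
      if ((max(recent) - min(recent)) / max(mean(recent), 1e-12) <
          config$early_stop_tol) {
        hist <- hist[seq_len(epoch)]
        break
      }
    }
    if (epoch == config$max_epochs) hist <- hist[seq_len(epoch)]
  }

  structure(list(G = G, F = F_, D_X = D_X, D_Y = D_Y,
                 history = do.call(rbind, hist), config = config),
            class = "translation_bundle")
}

#' Translate samples between domains
#'
#' Applies the trained mapping (`G` for dermo to macro, `F` for the
#' reverse). Translation is style-level: geometry is preserved, so each
#' sample's ground-truth mask is carried through unchanged. Output samples
#' are retagged `trans_macro` / `trans_dermo`.
#'
#' @param bundle a `translation_bundle` from [train_cyclegan()].
#' @param samples a `d2m_dataset` (images in `[-1,1]` at the trained size).
#' @param direction `"dermo2macro"` or `"macro2dermo"`.
#' @return a `d2m_dataset` of translated samples.
#' @export
translate <- function(bundle, samples,
                      direction = c("dermo2macro", "macro2dermo")) {
  direction <- match.arg(direction)
  stopifnot(inherits(bundle, "translation_bundle"))
  size <- bundle$config$gen_spec$input_size
  check_gan_range(samples, size, "input")
  net <- if (direction == "dermo2macro") bundle$G else bundle$F
  tag <- if (direction == "dermo2macro") "trans_macro" else "trans_dermo"
  out <- lapply(samples, function(s) {
    s$image <- net$forward(s$image)
    s$domain <- tag
    s
  })
  new_dataset(out)
}
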