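# A minimal CPU conv-net engine with explicit reverse-mode gradients.
#
# A module is an environment carrying `params`, matching `grads` (accumulated
# by backward), an optional `children` list, and `forward(x)` / `backward(dy)`
# closures. Images flow through as H x W x C arrays. Every layer caches what
# its last forward pass needs for the matching backward pass; the training
# loops below are ordered so a module is always backpropagated before it is
# re-used. Convolutions are im2col gathers + BLAS matmuls (see tensor-ops.R).

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m$params <- list()
  m$grads <- list()
  m$children <- list()
  class(m) <- "d2m_module"
  m
}

#' @export
print.d2m_module <- function(x, ...) {
  cat("<d2m_module:", x$type, "> params:", format(n_params(x), big.mark = ","),
      "\n")
  invisible(x)
}

collect_modules <- function(m) {
  out <- list(m)
  for (ch in m$children) out <- c(out, collect_modules(ch))
  out
}

#' Total number of trainable parameters in a network
#' @param m a network module.
#' @return integer parameter count.
#' @export
n_params <- function(m) {
  sum(vapply(collect_modules(m),
             function(x) sum(vapply(x$params, length, 1L)), 1))
}

zero_grads <- function(m) {
  for (mod in collect_modules(m))
    mod$grads <- lapply(mod$params, function(p) array(0, dim(p) %||% length(p)))
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_state <- function(m) lapply(collect_modules(m), function(x) x$params)

set_state <- function(m, state) {
  mods <- collect_modules(m)
  stopifnot(length(mods) == length(state))
  for (i in seq_along(mods)) mods[[i]]$params <- state[[i]]
  invisible(m)
}

# cached conv maps, keyed by input size, live on the module
module_map <- function(m, in_h, in_w, k, stride, pad, dilation) {
  key <- paste(in_h, in_w, sep = "x")
  if (is.null(m$maps)) m$maps <- list()
  if (is.null(m$maps[[key]]))
    m$maps[[key]] <- conv_index_map(in_h, in_w, k, stride, pad, dilation)
  m$maps[[key]]
}

scatter_rows <- function(dM, group, n_rows) {
  rs <- rowsum(dM, group = group)
  out <- matrix(0, n_rows, ncol(dM))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# ---- convolution ------------------------------------------------------------

# init_sd = NULL -> He initialisation; otherwise fixed Gaussian sd (GANs use
# sd 0.02 following the training protocol of the translator).
layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, dilation = 1L,
                       bias = TRUE, init_sd = NULL) {
  m <- new_module("conv")
  m$hyper <- list(in_ch = in_ch, out_ch = out_ch, k = k, stride = stride,
                  pad = pad, dilation = dilation)
  sd <- init_sd %||% sqrt(2 / (k * k * in_ch))
  m$params$W <- matrix(stats::rnorm(k * k * in_ch * out_ch, 0, sd),
                       k * k * in_ch, out_ch)
  if (bias) m$params$b <- numeric(out_ch)
  zero_grads(m)
  m$forward <- function(x) {
    h <- m$hyper
    stopifnot(dim(x)[3L] == h$in_ch)
    map <- module_map(m, dim(x)[1L], dim(x)[2L], h$k, h$stride, h$pad,
                      h$dilation)
    X <- matrix(x, dim(x)[1L] * dim(x)[2L], h$in_ch)
    P <- im2col(X, map)
    out <- P %*% m$params$W
    if (!is.null(m$params$b)) out <- sweep(out, 2L, m$params$b, `+`)
    m$cache <- list(P = P, map = map, in_dim = dim(x))
    array(out, c(map$out_h, map$out_w, h$out_ch))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dY <- matrix(dy, cc$map$out_h * cc$map$out_w, m$hyper$out_ch)
    m$grads$W <- m$grads$W + crossprod(cc$P, dY)
    if (!is.null(m$params$b)) m$grads$b <- m$grads$b + colSums(dY)
    dP <- tcrossprod(dY, m$params$W)
    dX <- col2im(dP, cc$map)
    array(dX, cc$in_dim)
  }
  m
}

# Transposed convolution producing exactly stride * input size (the adjoint of
# a stride-s, pad-1 convolution; equivalent to output_padding = 1).
layer_conv_transpose <- function(in_ch, out_ch, k = 3L, stride = 2L, pad = 1L,
                                 bias = TRUE, init_sd = NULL) {
  m <- new_module("conv_transpose")
  m$hyper <- list(in_ch = in_ch, out_ch = out_ch, k = k, stride = stride,
                  pad = pad)
  sd <- init_sd %||% sqrt(2 / (k * k * in_ch))
  m$params$W <- matrix(stats::rnorm(k * k * out_ch * in_ch, 0, sd),
                       k * k * out_ch, in_ch)
  if (bias) m$params$b <- numeric(out_ch)
  zero_grads(m)
  m$forward <- function(x) {
    h <- m$hyper
    stopifnot(dim(x)[3L] == h$in_ch)
    out_h <- dim(x)[1L] * h$stride
    out_w <- dim(x)[2L] * h$stride
    map <- module_map(m, out_h, out_w, h$k, h$stride, h$pad, 1L)
    stopifnot(nrow(map$M) == dim(x)[1L] * dim(x)[2L])
    X <- matrix(x, dim(x)[1L] * dim(x)[2L], h$in_ch)
    G <- tcrossprod(X, m$params$W)            # [n_in, k2*out_ch]
    Y <- col2im(G, map)                       # [out_h*out_w, out_ch]
    if (!is.null(m$params$b)) Y <- sweep(Y, 2L, m$params$b, `+`)
    m$cache <- list(X = X, map = map, in_dim = dim(x))
    array(Y, c(out_h, out_w, h$out_ch))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    h <- m$hyper
    dY <- matrix(dy, cc$map$in_h * cc$map$in_w, h$out_ch)
    P <- im2col(dY, cc$map)                   # [n_in, k2*out_ch]
    m$grads$W <- m$grads$W + crossprod(P, cc$X)
    if (!is.null(m$params$b)) m$grads$b <- m$grads$b + colSums(dY)
    dX <- P %*% m$params$W
    array(dX, cc$in_dim)
  }
  m
}

# Depthwise 3x3 convolution (one filter per channel), MobileNetV2-style.
layer_dwconv <- function(ch, k = 3L, stride = 1L, pad = 1L, dilation = 1L,
                         bias = TRUE, init_sd = NULL) {
  m <- new_module("dwconv")
  m$hyper <- list(ch = ch, k = k, stride = stride, pad = pad,
                  dilation = dilation)
  sd <- init_sd %||% sqrt(2 / (k * k))
  m$params$W <- matrix(stats::rnorm(k * k * ch, 0, sd), k * k, ch)
  if (bias) m$params$b <- numeric(ch)
  zero_grads(m)
  m$forward <- function(x) {
    h <- m$hyper
    stopifnot(dim(x)[3L] == h$ch)
    map <- module_map(m, dim(x)[1L], dim(x)[2L], h$k, h$stride, h$pad,
                      h$dilation)
    X <- matrix(x, dim(x)[1L] * dim(x)[2L], h$ch)
    P <- im2col(X, map)
    n_out <- nrow(map$M)
    out <- matrix(0, n_out, h$ch)
    sel0 <- (seq_len(h$ch) - 1L) * map$k2
    for (a in seq_len(map$k2))
      out <- out + P[, sel0 + a, drop = FALSE] *
        matrix(m$params$W[a, ], n_out, h$ch, byrow = TRUE)
    if (!is.null(m$params$b)) out <- sweep(out, 2L, m$params$b, `+`)
    m$cache <- list(P = P, map = map, in_dim = dim(x), sel0 = sel0)
    array(out, c(map$out_h, map$out_w, h$ch))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    h <- m$hyper
    n_out <- nrow(cc$map$M)
    dY <- matrix(dy, n_out, h$ch)
    dP <- matrix(0, n_out, cc$map$k2 * h$ch)
    for (a in seq_len(cc$map$k2)) {
      sel <- cc$sel0 + a
      dP[, sel] <- dY * matrix(m$params$W[a, ], n_out, h$ch, byrow = TRUE)
      m$grads$W[a, ] <- m$grads$W[a, ] +
        colSums(cc$P[, sel, drop = FALSE] * dY)
    }
    if (!is.null(m$params$b)) m$grads$b <- m$grads$b + colSums(dY)
    dX <- col2im(dP, cc$map)
    array(dX, cc$in_dim)
  }
  m
}

# ---- normalisation and activations -----------------------------------------

layer_instnorm <- function(ch, eps = 1e-5) {
  m <- new_module("instnorm")
  m$hyper <- list(ch = ch, eps = eps)
  m$params$gamma <- rep(1, ch)
  m$params$beta <- rep(0, ch)
  zero_grads(m)
  m$forward <- function(x) {
    d <- dim(x)
    N <- d[1L] * d[2L]
    X <- matrix(x, N, d[3L])
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + m$hyper$eps)
    xhat <- sweep(xc, 2L, inv, `*`)
    Y <- sweep(sweep(xhat, 2L, m$params$gamma, `*`), 2L, m$params$beta, `+`)
    m$cache <- list(xhat = xhat, inv = inv, N = N, dims = d)
    array(Y, d)
  }
  m$backward <- function(dy) {
    cc <- m$cache
    dY <- matrix(dy, cc$N, cc$dims[3L])
    m$grads$gamma <- m$grads$gamma + colSums(dY * cc$xhat)
    m$grads$beta <- m$grads$beta + colSums(dY)
    dxhat <- sweep(dY, 2L, m$params$gamma, `*`)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cc$xhat)
    dX <- sweep(dxhat, 2L, s1) - sweep(cc$xhat, 2L, s2, `*`)
    dX <- sweep(dX, 2L, cc$inv, `*`)
    array(dX, cc$dims)
  }
  m
}

layer_act <- function(kind, slope = 0.2) {
  m <- new_module(paste0("act_", kind))
  m$forward <- switch(kind,
    relu = function(x) { m$cache <- x > 0; x * m$cache },
    relu6 = function(x) { m$cache <- x > 0 & x < 6; clamp(x, 0, 6) },
    lrelu = function(x) { m$cache <- x > 0; ifelse(m$cache, x, slope * x) },
    tanh = function(x) { y <- tanh(x); m$cache <- y; y },
    sigmoid = function(x) { y <- 1 / (1 + exp(-x)); m$cache <- y; y },
    stop("unknown activation ", kind))
  m$backward <- switch(kind,
    relu = ,
    relu6 = function(dy) dy * m$cache,
    lrelu = function(dy) ifelse(m$cache, dy, slope * dy),
    tanh = function(dy) dy * (1 - m$cache^2),
    sigmoid = function(dy) dy * m$cache * (1 - m$cache))
  m
}

layer_pad_reflect <- function(p) {
  m <- new_module("pad_reflect")
  m$hyper <- list(p = p)
  reflect_idx <- function(n, p) {
    s <- seq_len(n + 2L * p) - p
    s[s < 1L] <- 2L - s[s < 1L]
    s[s > n] <- 2L * n - s[s > n]
    s
  }
  m$forward <- function(x) {
    d <- dim(x)
    p <- m$hyper$p
    stopifnot(d[1L] > p, d[2L] > p)
    ys <- reflect_idx(d[1L], p)
    xs <- reflect_idx(d[2L], p)
    m$cache <- list(dims = d, ys = ys, xs = xs)
    x[ys, xs, , drop = FALSE]
  }
  m$backward <- function(dy) {
    cc <- m$cache
    d <- cc$dims
    n_pad <- length(cc$ys) * length(cc$xs)
    dY <- matrix(dy, n_pad, d[3L])
    src_y <- rep(cc$ys, times = length(cc$xs))
    src_x <- rep(cc$xs, each = length(cc$ys))
    group <- (src_x - 1L) * d[1L] + src_y
    dX <- scatter_rows(dY, group, d[1L] * d[2L])
    array(dX, d)
  }
  m
}

layer_upsample <- function(scale) {
  m <- new_module("upsample")
  m$hyper <- list(scale = scale)
  m$forward <- function(x) {
    d <- dim(x)
    key <- paste(d[1L], d[2L], sep = "x")
    if (is.null(m$maps)) m$maps <- list()
    if (is.null(m$maps[[key]]))
      m$maps[[key]] <- bilinear_map(d[1L], d[2L], d[1L] * m$hyper$scale,
                                    d[2L] * m$hyper$scale)
    map <- m$maps[[key]]
    X <- matrix(x, d[1L] * d[2L], d[3L])
    Y <- X[map$idx[, 1L], , drop = FALSE] * map$w[, 1L] +
      X[map$idx[, 2L], , drop = FALSE] * map$w[, 2L] +
      X[map$idx[, 3L], , drop = FALSE] * map$w[, 3L] +
      X[map$idx[, 4L], , drop = FALSE] * map$w[, 4L]
    m$cache <- list(map = map, dims = d)
    array(Y, c(map$out_h, map$out_w, d[3L]))
  }
  m$backward <- function(dy) {
    cc <- m$cache
    map <- cc$map
    dY <- matrix(dy, map$out_h * map$out_w, cc$dims[3L])
    n_in <- cc$dims[1L] * cc$dims[2L]
    dX <- matrix(0, n_in, cc$dims[3L])
    for (t in 1:4)
      dX <- dX + scatter_rows(dY * map$w[, t], map$idx[, t], n_in)
    array(dX, cc$dims)
  }
  m
}

# ---- composites -------------------------------------------------------------

layer_seq <- function(...) {
  m <- new_module("seq")
  m$children <- list(...)
  m$forward <- function(x) {
    for (ch in m$children) x <- ch$forward(x)
    x
  }
  m$backward <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$backward(dy)
    dy
  }
  m
}

residual_block <- function(ch, init_sd = NULL) {
  m <- new_module("residual")
  body <- layer_seq(
    layer_conv(ch, ch, 3L, pad = 1L, init_sd = init_sd),
    layer_instnorm(ch),
    layer_act("relu"),
    layer_conv(ch, ch, 3L, pad = 1L, init_sd = init_sd),
    layer_instnorm(ch))
  m$children <- list(body)
  m$forward <- function(x) x + body$forward(x)
  m$backward <- function(dy) dy + body$backward(dy)
  m
}

# MobileNetV2 inverted residual: pointwise expand, depthwise, pointwise
# project (linear), skip connection when the shape is preserved.
inverted_residual <- function(in_ch, out_ch, stride = 1L, expand = 6L) {
  m <- new_module("inverted_residual")
  mid <- in_ch * expand
  layers <- list()
  if (expand != 1L)
    layers <- c(layers, list(layer_conv(in_ch, mid, 1L),
                             layer_instnorm(mid), layer_act("relu6")))
  layers <- c(layers, list(
    layer_dwconv(mid, 3L, stride = stride, pad = 1L),
    layer_instnorm(mid), layer_act("relu6"),
    layer_conv(mid, out_ch, 1L), layer_instnorm(out_ch)))
  body <- do.call(layer_seq, layers)
  m$children <- list(body)
  m$use_skip <- stride == 1L && in_ch == out_ch
  m$forward <- function(x) if (m$use_skip) x + body$forward(x) else body$forward(x)
  m$backward <- function(dy) if (m$use_skip) dy + body$backward(dy) else body$backward(dy)
  m
}

# ---- optimiser --------------------------------------------------------------

make_adam <- function(nets, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  if (inherits(nets, "d2m_module")) nets <- list(nets)
  opt <- new.env(parent = emptyenv())
  opt$modules <- unlist(lapply(nets, collect_modules))
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$state <- lapply(opt$modules, function(m)
    lapply(m$params, function(p) list(m = p * 0, v = p * 0)))
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$modules)) {
    mod <- opt$modules[[i]]
    for (nm in names(mod$params)) {
      g <- mod$grads[[nm]]
      st <- opt$state[[i]][[nm]]
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      opt$state[[i]][[nm]] <- st
      mod$params[[nm]] <- mod$params[[nm]] -
        opt$lr * (st$m / bc1) / (sqrt(st$v / bc2) + opt$eps)
    }
  }
  invisible(opt)
}
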