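# Low-level array machinery shared by every network in the package.
#
# Convention (asserted throughout): images are H x W x C double arrays,
# column-major, so a pixel (h, w) has linear index (w-1)*H + h. A feature map
# flattened to a matrix is [H*W, C]. Convolutions are realised as im2col
# gather + one BLAS matmul; the gather map is precomputed once per
# (input size, kernel geometry) pair and cached on the layer.

# Index map for a 2-D convolution window walk.
# Returns out_h, out_w and M: an (n_out x k*k) integer matrix of linear input
# pixel indices, 0 where the tap falls in the zero padding.
conv_index_map <- function(in_h, in_w, k, stride = 1L, pad = 0L, dilation = 1L) {
  eff <- (k - 1L) * dilation + 1L
  out_h <- (in_h + 2L * pad - eff) %/% stride + 1L
  out_w <- (in_w + 2L * pad - eff) %/% stride + 1L
  if (out_h < 1L || out_w < 1L)
    stop("input ", in_h, "x", in_w, " too small for kernel ", k,
         " (dilation ", dilation, ")")
  oy <- rep(seq_len(out_h), times = out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  ky <- rep(seq_len(k), times = k)
  kx <- rep(seq_len(k), each = k)
  iy <- outer((oy - 1L) * stride - pad, (ky - 1L) * dilation + 1L, `+`)
  ix <- outer((ox - 1L) * stride - pad, (kx - 1L) * dilation + 1L, `+`)
  valid <- iy >= 1L & iy <= in_h & ix >= 1L & ix <= in_w
  M <- ifelse(valid, (ix - 1L) * in_h + iy, 0L)
  storage.mode(M) <- "integer"
  list(in_h = in_h, in_w = in_w, out_h = out_h, out_w = out_w,
       k2 = k * k, M = M, group = as.vector(M) + 1L)
}

# Gather patches: X is [H*W, C]; result is [n_out, k2*C] with column order
# (channel-major blocks of k2 taps), matching the weight layout [k2*C_in, C_out].
im2col <- function(X, map) {
  C <- ncol(X)
  Xp <- rbind(matrix(0, 1L, C), X)           # row 1 absorbs padding taps
  P <- Xp[as.vector(map$M) + 1L, , drop = FALSE]
  dim(P) <- NULL
  matrix(P, nrow(map$M), map$k2 * C)
}

# Scatter-add adjoint of im2col: dP is [n_out, k2*C]; returns [H*W, C].
col2im <- function(dP, map) {
  n_out <- nrow(map$M)
  C <- ncol(dP) %/% map$k2
  # (n_out, k2*C) and (n_out*k2, C) share the same column-major memory layout
  dPm <- matrix(as.vector(dP), n_out * map$k2, C)
  rs <- rowsum(dPm, group = map$group)
  out <- matrix(0, map$in_h * map$in_w + 1L, C)
  out[as.integer(rownames(rs)), ] <- rs
  out[-1L, , drop = FALSE]
}

# Relative luminance (Rec. 601 weights), for H x W x 3 arrays or flat matrices.
luminance <- function(img) {
  if (length(dim(img)) == 3L)
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  else
    stop("luminance() expects an H x W x 3 array")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Sampling weights for separable bilinear interpolation with half-pixel
# centres: source coordinate of output pixel i is (i - 0.5) * in/out + 0.5.
bilinear_axis <- function(n_in, n_out) {
  s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
  i0 <- floor(s)
  f <- s - i0
  lo <- clamp(i0, 1, n_in)
  hi <- clamp(i0 + 1, 1, n_in)
  # collapse the fraction at the borders where both taps clamp to the same pixel
  f[lo == hi] <- 0
  list(lo = as.integer(lo), hi = as.integer(hi), f = f)
}

#' Bilinear image resize
#'
#' Resizes an `H x W x C` array (or `H x W` matrix) to `out_h x out_w` using
#' separable bilinear interpolation with half-pixel-centre alignment.
#'
#' @param img numeric array `H x W x C` or matrix `H x W`.
#' @param out_h,out_w output dimensions in pixels.
#' @return resized array of the same rank as the input.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  is_mat <- is.matrix(img)
  if (is_mat) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  ay <- bilinear_axis(d[1L], out_h)
  ax <- bilinear_axis(d[2L], out_w)
  wy <- ay$f; wx <- ax$f
  out <- array(0, c(out_h, out_w, d[3L]))
  w00 <- outer(1 - wy, 1 - wx)
  w10 <- outer(wy, 1 - wx)
  w01 <- outer(1 - wy, wx)
  w11 <- outer(wy, wx)
  for (c in seq_len(d[3L])) {
    out[, , c] <- img[ay$lo, ax$lo, c] * w00 + img[ay$hi, ax$lo, c] * w10 +
      img[ay$lo, ax$hi, c] * w01 + img[ay$hi, ax$hi, c] * w11
  }
  if (is_mat) out <- out[, , 1L]
  out
}

# Precomputed four-tap form of bilinear_resize for use as a network layer
# (forward = sparse gather, backward = weighted scatter with rowsum).
bilinear_map <- function(in_h, in_w, out_h, out_w) {
  ay <- bilinear_axis(in_h, out_h)
  ax <- bilinear_axis(in_w, out_w)
  oy_lo <- rep(ay$lo, times = out_w); oy_hi <- rep(ay$hi, times = out_w)
  ox_lo <- rep(ax$lo, each = out_h);  ox_hi <- rep(ax$hi, each = out_h)
  fy <- rep(ay$f, times = out_w); fx <- rep(ax$f, each = out_h)
  idx <- cbind((ox_lo - 1L) * in_h + oy_lo, (ox_lo - 1L) * in_h + oy_hi,
               (ox_hi - 1L) * in_h + oy_lo, (ox_hi - 1L) * in_h + oy_hi)
  w <- cbind((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  list(in_h = in_h, in_w = in_w, out_h = out_h, out_w = out_w,
       idx = idx, w = w)
}
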