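# Independent brute-force oracles used against the package implementations.
# These deliberately use naive loops / queues rather than the vectorised
# code paths they check.

# connected components of a binary matrix by BFS flood fill
flood_components <- function(mask, connectivity = 4) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  if (connectivity == 4) {
    moves <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    moves <- as.matrix(expand.grid(-1:1, -1:1))
    moves <- moves[rowSums(abs(moves)) > 0, ]
  }
  for (start in which(mask > 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1L]
      queue <- queue[-1L]
      i <- (p - 1L) %% nrow(mask) + 1L
      j <- (p - 1L) %/% nrow(mask) + 1L
      for (k in seq_len(nrow(moves))) {
        ii <- i + moves[k, 1L]
        jj <- j + moves[k, 2L]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] > 0) {
          q <- (jj - 1L) * nrow(mask) + ii
          if (lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  list(labels = lab, n = nxt)
}

# naive per-pixel bilinear resize, half-pixel centres, coded independently
bilinear_oracle <- function(img, out_h, out_w) {
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  out <- array(0, c(out_h, out_w, C))
  for (oy in seq_len(out_h)) {
    for (ox in seq_len(out_w)) {
      sy <- (oy - 0.5) * H / out_h + 0.5
      sx <- (ox - 0.5) * W / out_w + 0.5
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      y0c <- min(max(y0, 1), H); y1c <- min(max(y0 + 1, 1), H)
      x0c <- min(max(x0, 1), W); x1c <- min(max(x0 + 1, 1), W)
      if (y0c == y1c) fy <- 0
      if (x0c == x1c) fx <- 0
      for (c in seq_len(C)) {
        out[oy, ox, c] <-
          img[y0c, x0c, c] * (1 - fy) * (1 - fx) +
          img[y1c, x0c, c] * fy * (1 - fx) +
          img[y0c, x1c, c] * (1 - fy) * fx +
          img[y1c, x1c, c] * fy * fx
      }
    }
  }
  out
}

# exhaustive search for the largest centred box with bright corner patches
exhaustive_corner_box <- function(image, threshold, corner_fraction) {
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  H <- nrow(lum); W <- ncol(lum)
  for (m in 0:((min(H, W) - 32) %/% 2)) {
    h <- H - 2 * m; w <- W - 2 * m
    ph <- max(1, floor(h * corner_fraction))
    pw <- max(1, floor(w * corner_fraction))
    rows_t <- (m + 1):(m + ph); rows_b <- (m + h - ph + 1):(m + h)
    cols_l <- (m + 1):(m + pw); cols_r <- (m + w - pw + 1):(m + w)
    corners <- c(mean(lum[rows_t, cols_l]), mean(lum[rows_t, cols_r]),
                 mean(lum[rows_b, cols_l]), mean(lum[rows_b, cols_r]))
    if (all(corners >= threshold)) return(c(m, m, h, w))
  }
  NULL
}

# per-pixel confusion counting by explicit loop
confusion_loop <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] > 0
      t <- truth[i, j] > 0
      if (p && t) tp <- tp + 1L
      else if (p && !t) fp <- fp + 1L
      else if (!p && t) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# finite-difference gradient of sum(net(x)^2)/2 at a few coordinates
fd_input_grad <- function(net, x, coords, eps = 1e-5) {
  vapply(coords, function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (sum(net$forward(xp)^2) - sum(net$forward(xm)^2)) / (4 * eps)
  }, 0)
}

# dataset range conversions used across tests
sym_ds <- function(ds) {
  structure(lapply(ds, function(s) { s$image <- 2 * s$image - 1; s }),
            class = "d2m_dataset")
}
unit_ds <- function(ds) {
  structure(lapply(ds, function(s) {
    s$image <- pmin(pmax((s$image + 1) / 2, 0), 1)
    s
  }), class = "d2m_dataset")
}

# small deterministic two-domain dataset for smoke training
smoke_domains <- function(n = 8, size = 32, seed = 5,
                          dermo_probs = c(dark_corners = 1, gel = 0,
                                          ruler = 0),
                          macro_probs = c(glare = 1, depth_shading = 0)) {
  generate_dataset(synthetic_config(
    n_images = n, image_size = size, seed = seed,
    dermo_probs = dermo_probs, macro_probs = macro_probs,
    split_fractions = c(train = 1)))
}
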