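# Dataset assembly and image preprocessing: dark-corner cropping, bilinear
# resizing with value-range mapping, and deterministic stratified splitting.
#
# Conventions asserted everywhere: images are H x W x 3 RGB arrays; pixel
# coordinates are 0-based, half-open; the adversarial branch works in
# [-1,1] (tanh generator output), the segmentation branch in [0,1]
# (sigmoid head).

#' Crop box (0-based, half-open)
#'
#' @param top,left top-left corner, 0-based.
#' @param height,width box extent in pixels; at least 32 each.
#' @return an object of class `crop_box`.
#' @export
crop_box <- function(top, left, height, width) {
  stopifnot(top >= 0, left >= 0, height >= 32, width >= 32)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(height), width = as.integer(width)),
            class = "crop_box")
}

whole_image_box <- function(image) crop_box(0L, 0L, dim(image)[1L],
                                            dim(image)[2L])

# summed-area table; patch means in O(1)
integral_image <- function(m) {
  cs <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))  # box sums from (1,1)
  rbind(0, cbind(0, cs))
}

patch_mean <- function(S, top, left, h, w) {
  # S is (H+1)x(W+1); box rows top+1..top+h (1-based), cols left+1..left+w
  (S[top + h + 1L, left + w + 1L] - S[top + 1L, left + w + 1L] -
     S[top + h + 1L, left + 1L] + S[top + 1L, left + 1L]) / (h * w)
}

#' Detect the dark-corner crop of a dermoscopic image
#'
#' Dermoscopic images frequently show dark circular corners from the scope's
#' field of view; these are removed by cropping before translation. This
#' operator automates the step: it returns the largest centred box whose four
#' corner patches (each `corner_fraction` of the box side) all have mean
#' luminance at least `darkness_threshold`. When the corners are already
#' bright the whole-image box is returned.
#'
#' @param image `H x W x 3` array in `[0,1]`, at least 64 x 64.
#' @param darkness_threshold corner luminance a box must reach, in `[0,1]`.
#' @param corner_fraction corner patch side as a fraction of the box side,
#'   in `(0, 0.5)`.
#' @return a [crop_box()].
#' @export
detect_dark_corners <- function(image, darkness_threshold = 0.25,
                                corner_fraction = 0.15) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  if (d[1L] < 64 || d[2L] < 64) stop("image must be at least 64 x 64")
  stopifnot(darkness_threshold >= 0, darkness_threshold <= 1,
            corner_fraction > 0, corner_fraction < 0.5)
  S <- integral_image(luminance(image))
  max_m <- (min(d[1L], d[2L]) - 32L) %/% 2L
  for (m in 0:max_m) {
    h <- d[1L] - 2L * m
    w <- d[2L] - 2L * m
    ph <- max(1L, as.integer(floor(h * corner_fraction)))
    pw <- max(1L, as.integer(floor(w * corner_fraction)))
    corners <- c(
      patch_mean(S, m, m, ph, pw),
      patch_mean(S, m, m + w - pw, ph, pw),
      patch_mean(S, m + h - ph, m, ph, pw),
      patch_mean(S, m + h - ph, m + w - pw, ph, pw))
    if (all(corners >= darkness_threshold))
      return(crop_box(m, m, h, w))
  }
  stop("uncroppable: no centred box of at least 32 x 32 has bright corners")
}

#' Crop an image (and optionally its mask) to a box
#'
#' Image and mask are cropped identically; cropping can only remove mask
#' foreground, never add it.
#'
#' @param image `H x W x 3` array.
#' @param box a [crop_box()].
#' @param mask optional `H x W` binary matrix.
#' @return the cropped image, or `list(image, mask)` when a mask is given.
#' @export
crop <- function(image, box, mask = NULL) {
  stopifnot(inherits(box, "crop_box"))
  d <- dim(image)
  if (box$top + box$height > d[1L] || box$left + box$width > d[2L])
    stop("crop box exceeds image bounds")
  rows <- (box$top + 1L):(box$top + box$height)
  cols <- (box$left + 1L):(box$left + box$width)
  out <- image[rows, cols, , drop = FALSE]
  if (is.null(mask)) return(out)
  stopifnot(all(dim(mask) == d[1:2]))
  list(image = out, mask = mask[rows, cols, drop = FALSE])
}

#' Resize an image and map its value range
#'
#' Bilinear resize to `target_size x target_size`, then map `[0,1]` input
#' values to the requested working range: `"unit"` keeps `[0,1]` (the
#' segmentation branch), `"sym"` maps to `[-1,1]` (the adversarial branch,
#' matching the generator's tanh output).
#'
#' @param image `H x W x 3` array with values in `[0,1]`.
#' @param target_size output side in pixels.
#' @param value_range `"unit"` for `[0,1]` or `"sym"` for `[-1,1]`.
#' @return a `target_size x target_size x 3` array.
#' @export
resize_and_scale <- function(image, target_size,
                             value_range = c("unit", "sym")) {
  if (target_size <= 0) stop("target_size must be positive")
  value_range <- match.arg(value_range)
  d <- dim(image)
  out <- if (d[1L] == target_size && d[2L] == target_size) image
  else bilinear_resize(image, target_size, target_size)
  if (value_range == "sym") 2 * out - 1 else out
}

to_unit <- function(image) (image + 1) / 2
to_sym <- function(image) 2 * image - 1

# largest-remainder apportionment of n into fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign train/val/test split tags
#'
#' Deterministic, optionally stratified assignment. Within every stratum the
#' per-split counts follow `fractions` by largest-remainder rounding, so a
#' 90/10 request on 100 samples gives exactly 90/10 and a 50/50 request on 80
#' samples gives 40/40. Every sample lands in exactly one split.
#'
#' @param dataset a `d2m_dataset`.
#' @param fractions named numeric summing to 1 (names become split tags).
#' @param stratify_key optional name of a sample field (e.g. a class label)
#'   to stratify on.
#' @param seed integer seed for the shuffle.
#' @return the dataset with `split` tags rewritten.
#' @export
split_dataset <- function(dataset, fractions = c(train = 0.9, val = 0.1),
                          stratify_key = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "d2m_dataset"),
            abs(sum(fractions) - 1) < 1e-9, !is.null(names(fractions)))
  strata <- if (is.null(stratify_key)) rep("all", length(dataset))
  else vapply(dataset, function(s) as.character(s[[stratify_key]] %||% "NA"),
              "")
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < length(fractions))
      warning("stratum '", st, "' has fewer samples (", length(idx),
              ") than splits; best-effort assignment")
    counts <- apportion(length(idx), fractions)
    shuffled <- with_seed(derive_seed(seed, paste0("split-", st)),
                          sample(idx))
    tags <- rep(names(fractions), counts)
    for (j in seq_along(shuffled))
      dataset[[shuffled[j]]]$split <- tags[j]
  }
  dataset
}

#' Subset a dataset by split tag or predicate
#' @param dataset a `d2m_dataset`.
#' @param split one or more split tags to keep.
#' @return the filtered `d2m_dataset`.
#' @export
dataset_subset <- function(dataset, split) {
  keep <- vapply(dataset, function(s) s$split %in% split, TRUE)
  new_dataset(unclass(dataset)[keep])
}
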