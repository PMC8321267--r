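# Quantitative evaluation: Frechet distance between embedded image sets
# (the FID construction with a pluggable embedder), the Variation Ratio
# comparing translated to reference distances, and the six-metric skin
# lesion segmentation suite (thresholded Jaccard, Jaccard, Dice, accuracy,
# sensitivity, specificity) with overlay rendering and normalized error
# rates.

#' Fixed random-projection image embedder
#'
#' A deterministic, download-free stand-in for a pretrained deep embedding:
#' images are bilinearly reduced to `patch x patch` and projected onto
#' `dim` fixed Gaussian directions (seeded once at construction). Linear in
#' the pixels, so it is sensitive to exactly the cues the synthetic domains
#' differ in (corner darkness, glare highlights, skin tone).
#'
#' @param dim embedding dimension.
#' @param seed seed fixing the projection.
#' @param patch downsampled side length.
#' @return a function mapping an `H x W x 3` array in `[0,1]` to a numeric
#'   vector of length `dim`.
#' @export
make_toy_embedder <- function(dim = 64L, seed = 42L, patch = 16L) {
  n_in <- 3L * patch * patch
  W <- with_seed(seed, matrix(stats::rnorm(n_in * dim, 0, 1 / sqrt(n_in)),
                              n_in, dim))
  function(image) {
    stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
    v <- as.vector(bilinear_resize(image, patch, patch))
    as.vector(crossprod(W, v))
  }
}

#' Embed an image set and fit Gaussian statistics
#'
#' @param samples a `d2m_dataset`, list of samples, or list of images.
#' @param embedder a function mapping one image to a fixed-length vector,
#'   e.g. [make_toy_embedder()].
#' @return a `feature_stats` object: mean vector `mu`, sample covariance
#'   `sigma` (denominator n - 1) and count `n`.
#' @export
embed_images <- function(samples, embedder) {
  imgs <- lapply(samples, function(s)
    if (is.list(s) && !is.null(s$image)) s$image else s)
  if (length(imgs) < 2)
    stop("need at least 2 samples to estimate a covariance")
  E <- t(vapply(imgs, embedder, numeric(length(embedder(imgs[[1L]])))))
  structure(list(mu = colMeans(E), sigma = stats::cov(E), n = nrow(E)),
            class = "feature_stats")
}

# symmetric PSD square root via eigendecomposition, with jitter
psd_sqrt <- function(S, eps = 1e-6) {
  S <- (S + t(S)) / 2 + diag(eps, nrow(S))
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussian feature fits
#'
#' `||mu_a - mu_b||^2 + Tr(Sigma_a + Sigma_b - 2 (Sigma_a Sigma_b)^{1/2})`,
#' the distance underlying the FID score. The matrix square root is
#' stabilised by symmetrisation (`A^{1/2} B A^{1/2}` form), clamping of
#' negative eigenvalues to zero (rank-deficient covariances are expected
#' when few images are embedded), and an optional tiny `eps` jitter on the
#' diagonal; the result is clamped at 0. The default jitter is small enough
#' that closed-form cases are reproduced to near machine precision.
#'
#' @param a,b `feature_stats` objects of equal dimension.
#' @param eps diagonal jitter for the matrix square root.
#' @return a nonnegative scalar.
#' @export
frechet_distance <- function(a, b, eps = 1e-12) {
  stopifnot(inherits(a, "feature_stats"), inherits(b, "feature_stats"))
  if (length(a$mu) != length(b$mu))
    stop("embedding dimensions differ: ", length(a$mu), " vs ", length(b$mu))
  d2 <- sum((a$mu - b$mu)^2)
  Sa_half <- psd_sqrt(a$sigma, eps)
  M <- Sa_half %*% b$sigma %*% Sa_half
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  tr_cov <- sum(sqrt(pmax(ev, 0)))
  max(0, d2 + sum(diag(a$sigma)) + sum(diag(b$sigma)) - 2 * tr_cov)
}

#' Convenience: Frechet distance between two image sets
#' @param samples_a,samples_b image sets (see [embed_images()]).
#' @param embedder embedding function.
#' @return nonnegative scalar distance.
#' @export
fid_between <- function(samples_a, samples_b,
                        embedder = make_toy_embedder()) {
  frechet_distance(embed_images(samples_a, embedder),
                   embed_images(samples_b, embedder))
}

round_half_away <- function(x, digits) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Variation Ratio between a reference and a translated distance
#'
#' `VR = (reference - value) / reference`: positive when translation moved
#' the two distributions closer than the untranslated reference pair.
#' Reported values are conventionally rounded to two decimals, half away
#' from zero; pass `digits = 2` to reproduce that.
#'
#' @param reference reference distance (original domain pair); must be > 0.
#' @param value distance of the translated pair.
#' @param digits optional rounding digits (half away from zero); `NULL`
#'   returns the raw ratio.
#' @return scalar VR.
#' @export
variation_ratio <- function(reference, value, digits = NULL) {
  if (!is.finite(reference) || reference <= 0)
    stop("reference distance must be a positive finite number")
  vr <- (reference - value) / reference
  if (is.null(digits)) vr else round_half_away(vr, digits)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary matrices of identical shape.
#' @return named integer vector `c(TP, FP, FN, TN)` summing to the pixel
#'   count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  p <- pred > 0
  t <- truth > 0
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

metrics_one <- function(cc) {
  ja <- if (cc[["TP"]] + cc[["FP"]] + cc[["FN"]] == 0) 1
  else cc[["TP"]] / (cc[["TP"]] + cc[["FP"]] + cc[["FN"]])
  di <- if (cc[["TP"]] + cc[["FP"]] + cc[["FN"]] == 0) 1
  else 2 * cc[["TP"]] / (2 * cc[["TP"]] + cc[["FP"]] + cc[["FN"]])
  ac <- (cc[["TP"]] + cc[["TN"]]) / sum(cc)
  se <- if (cc[["TP"]] + cc[["FN"]] == 0) 1
  else cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
  sp <- if (cc[["TN"]] + cc[["FP"]] == 0) 1
  else cc[["TN"]] / (cc[["TN"]] + cc[["FP"]])
  c(JA = ja, DI = di, AC = ac, SE = se, SP = sp)
}

as_pairs <- function(pairs, truths = NULL) {
  if (!is.null(truths)) pairs <- Map(function(p, t) list(pred = p, truth = t),
                                     pairs, truths)
  lapply(pairs, function(pr) {
    stopifnot(!is.null(pr$pred), !is.null(pr$truth))
    pr
  })
}

#' Segmentation metric suite
#'
#' Computes per image: Jaccard `JA = TP/(TP+FP+FN)`, Dice
#' `DI = 2TP/(2TP+FP+FN)`, accuracy, sensitivity, specificity; aggregates
#' are means over images. The thresholded Jaccard `TJA` zeroes every
#' per-image `JA` below `tja_threshold` (default 0.65) before averaging —
#' the skin-lesion-challenge measure of incorrectness. An image where both
#' masks are empty counts `JA = DI = SE = 1` (perfect trivial agreement).
#'
#' @param pairs list of `list(pred, truth)` binary-mask pairs (or a list of
#'   predictions with `truths` supplied separately).
#' @param truths optional list of truth masks matching `pairs`.
#' @param tja_threshold per-image Jaccard threshold for TJA.
#' @param aggregate `"per_image"` (mean of per-image metrics, the default)
#'   or `"pooled"` (metrics of summed pixel counts; TJA remains per-image
#'   by definition).
#' @return a `metrics_record`: aggregates `TJA, JA, DI, AC, SE, SP`, the
#'   per-image table, and total pixel counts.
#' @export
segmentation_metrics <- function(pairs, truths = NULL, tja_threshold = 0.65,
                                 aggregate = c("per_image", "pooled")) {
  aggregate <- match.arg(aggregate)
  pairs <- as_pairs(pairs, truths)
  if (length(pairs) == 0) stop("no mask pairs supplied")
  per <- t(vapply(pairs, function(pr) {
    cc <- confusion_counts(pr$pred, pr$truth)
    c(metrics_one(cc), cc)
  }, numeric(9)))
  per <- as.data.frame(per)
  per$TJA <- ifelse(per$JA < tja_threshold, 0, per$JA)
  totals <- colSums(per[, c("TP", "FP", "FN", "TN")])
  agg <- if (aggregate == "per_image")
    c(colMeans(per[, c("JA", "DI", "AC", "SE", "SP")]))
  else metrics_one(totals)
  structure(list(TJA = mean(per$TJA), JA = agg[["JA"]], DI = agg[["DI"]],
                 AC = agg[["AC"]], SE = agg[["SE"]], SP = agg[["SP"]],
                 per_image = per, counts = totals,
                 tja_threshold = tja_threshold, aggregate = aggregate),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("TJA %.4f  JA %.4f  DI %.4f  AC %.4f  SE %.4f  SP %.4f  (%d images)\n",
              x$TJA, x$JA, x$DI, x$AC, x$SE, x$SP, nrow(x$per_image)))
  invisible(x)
}

#' Color-coded prediction/truth overlay
#'
#' Yellow where both masks agree on lesion (true positives), red where the
#' prediction over-segments (false positives), green where it
#' under-segments (false negatives), black elsewhere.
#'
#' @param pred,truth binary masks of identical shape.
#' @return an `H x W x 3` RGB array with the exact color table above.
#' @export
overlay <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  p <- pred > 0
  t <- truth > 0
  img <- array(0, c(dim(pred), 3L))
  img[, , 1L] <- (p & t) | (p & !t)        # red channel: TP + FP
  img[, , 2L] <- (p & t) | (!p & t)        # green channel: TP + FN
  img
}

#' Normalized false positive / false negative rates
#'
#' Per image, FP and FN pixel counts are divided by a normalizer and
#' averaged over images. The default normalizer is the ground-truth
#' foreground area; `"total"` divides by the full pixel count instead.
#' Images with empty ground truth are skipped under the foreground
#' normalizer.
#'
#' @inheritParams segmentation_metrics
#' @param normalizer `"foreground"` or `"total"`.
#' @return named vector `c(fp, fn)`.
#' @export
normalized_error_rates <- function(pairs, truths = NULL,
                                   normalizer = c("foreground", "total")) {
  normalizer <- match.arg(normalizer)
  pairs <- as_pairs(pairs, truths)
  rates <- vapply(pairs, function(pr) {
    cc <- confusion_counts(pr$pred, pr$truth)
    den <- if (normalizer == "foreground") cc[["TP"]] + cc[["FN"]]
    else sum(cc)
    if (den == 0) return(c(NA_real_, NA_real_))
    c(cc[["FP"]] / den, cc[["FN"]] / den)
  }, numeric(2))
  c(fp = mean(rates[1L, ], na.rm = TRUE),
    fn = mean(rates[2L, ], na.rm = TRUE))
}

#' Published FID reference values bundled with the package
#'
#' The printed Frechet Inception Distance values of the original study's
#' evaluation tables (test-subset comparisons and segmentation-set
#' comparisons), used as inputs for Variation Ratio worked examples.
#'
#' @return a data frame with columns `subset`, `preprocessing`, `pair`,
#'   `fid`.
#' @export
fid_reference_table <- function() {
  path <- system.file("extdata", "fid_published.csv", package = "derm2macro")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
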