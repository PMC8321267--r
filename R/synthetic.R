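# Synthetic two-domain skin lesion generator.
#
# Images emulate the structural cues that distinguish the two acquisition
# modalities: dermoscopic renders carry pigment-network texture and may add
# dark circular corners, a gel-blur patch or ruler ticks; macroscopic renders
# use a warmer skin tone and may add specular glare highlights and a signed
# depth-shading gradient across the lesion. The three dermoscope artifacts
# never occur in macroscopic renders and vice versa — that asymmetry is the
# learnable signal for the domain translator.

#' Lesion shape specification
#'
#' The lesion boundary is a star-convex radial function
#' `r(theta) = radius + sum_i amp_i * cos((i + 1) * theta + phase_i)`,
#' a minimal shape family producing irregular, diffuse-border-like outlines.
#'
#' @param center fractional image coordinates `(x, y)` in `[0,1]^2`.
#' @param radius base radius as a fraction of the image side, in `(0.05, 0.45)`.
#' @param boundary_harmonics list of `c(amplitude, phase)` pairs; amplitudes
#'   must sum to less than `radius` so the region stays simply connected.
#' @param base_color lesion RGB in `[0,1]`; must be darker than the rendering
#'   skin tone on all channels.
#' @param texture_strength nonnegative scalar scaling the pigment-network
#'   texture contrast.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center = c(0.5, 0.5), radius = 0.25,
                        boundary_harmonics = list(),
                        base_color = c(0.35, 0.22, 0.16),
                        texture_strength = 1) {
  stopifnot(length(center) == 2, all(center >= 0), all(center <= 1),
            length(base_color) == 3, all(base_color >= 0), all(base_color <= 1),
            texture_strength >= 0)
  if (radius <= 0.05 || radius >= 0.45)
    stop("lesion radius must lie in (0.05, 0.45), got ", radius)
  amps <- vapply(boundary_harmonics, `[`, 0, 1L)
  if (length(amps) && sum(abs(amps)) >= radius)
    stop("harmonic amplitudes must sum to less than the radius")
  structure(list(center = center, radius = radius,
                 boundary_harmonics = boundary_harmonics,
                 base_color = base_color,
                 texture_strength = texture_strength),
            class = "lesion_spec")
}

#' Rendering artifact configuration
#'
#' Dermoscopic-only artifacts: `dark_corners`, `gel`, `ruler`. Macroscopic-only
#' artifacts: `glare`, `depth_shading`. The renderers enforce this contract.
#'
#' @param dark_corners darken the circular field-of-view border (dermoscopic).
#' @param corner_darkness luminance level of the darkened corners, `< 0.1`
#'   by default so corner pixels read as black.
#' @param gel apply a local blur patch emulating immersion gel.
#' @param gel_blur box blur radius in pixels for the gel patch.
#' @param ruler draw periodic dark ruler ticks along the top edge.
#' @param glare add localized specular highlights (macroscopic).
#' @param glare_count number of highlights.
#' @param glare_intensity additive peak intensity of each highlight.
#' @param depth_shading impose a signed luminance gradient across the lesion.
#' @param depth_strength relative amplitude of the shading gradient.
#' @param skin_tone background skin RGB in `[0,1]`.
#' @return an object of class `artifact_config`.
#' @export
artifact_config <- function(dark_corners = FALSE, corner_darkness = 0.03,
                            gel = FALSE, gel_blur = 2L,
                            ruler = FALSE,
                            glare = FALSE, glare_count = 1L,
                            glare_intensity = 0.9,
                            depth_shading = FALSE, depth_strength = 0.25,
                            skin_tone = c(0.85, 0.72, 0.62)) {
  stopifnot(corner_darkness >= 0, corner_darkness < 0.1,
            gel_blur >= 1, glare_count >= 1, glare_intensity > 0,
            depth_strength >= 0, length(skin_tone) == 3,
            all(skin_tone >= 0), all(skin_tone <= 1))
  structure(list(dark_corners = dark_corners,
                 corner_darkness = corner_darkness,
                 gel = gel, gel_blur = as.integer(gel_blur), ruler = ruler,
                 glare = glare, glare_count = as.integer(glare_count),
                 glare_intensity = glare_intensity,
                 depth_shading = depth_shading,
                 depth_strength = depth_strength,
                 skin_tone = skin_tone),
            class = "artifact_config")
}

# fractional pixel-centre coordinate grids for a size x size image
coord_grid <- function(size) {
  v <- (seq_len(size) - 0.5) / size
  list(x = matrix(v, size, size, byrow = TRUE),
       y = matrix(v, size, size))
}

# continuous inside-ness: (boundary radius - pixel radius) in pixel units
lesion_signed_margin <- function(spec, size) {
  g <- coord_grid(size)
  dx <- g$x - spec$center[1L]
  dy <- g$y - spec$center[2L]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx)
  rb <- spec$radius
  hs <- spec$boundary_harmonics
  for (i in seq_along(hs))
    rb <- rb + hs[[i]][1L] * cos((i + 1) * theta + hs[[i]][2L])
  (rb - r) * size
}

#' Generate a binary lesion mask
#'
#' Rasterises the star-convex boundary of a [lesion_spec()] onto a
#' `size x size` grid. The result is a single 4-connected foreground
#' component by construction (the region is star-shaped about its centre).
#'
#' @param spec a [lesion_spec()].
#' @param size image side in pixels, at least 32.
#' @param rng_seed integer seed (kept for interface symmetry; the mask is a
#'   deterministic function of `spec`).
#' @return a `size x size` integer matrix with values 0/1.
#' @export
generate_lesion_mask <- function(spec, size, rng_seed = 0L) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (size < 32) stop("mask size must be at least 32 pixels")
  mask <- (lesion_signed_margin(spec, size) >= 0) * 1L
  frac <- mean(mask)
  if (frac <= 0.005 || frac >= 0.65)
    stop("degenerate lesion spec: foreground fraction ", signif(frac, 3),
         " outside (0.005, 0.65)")
  mask
}

# separable box blur with edge replication, radius r
box_blur <- function(mat, r) {
  n <- 2L * r + 1L
  blur1 <- function(m) {
    H <- nrow(m)
    padded <- m[clamp(seq(1L - r, H + r), 1L, H), , drop = FALSE]
    cs <- apply(padded, 2L, cumsum)
    (rbind(cs[(n):(H + 2L * r), , drop = FALSE]) -
       rbind(0, cs[seq_len(H + 2L * r - n), , drop = FALSE])) / n
  }
  t(blur1(t(blur1(mat))))
}

# pigment-network texture field: thresholded smoothed noise, 0/1-ish mesh
pigment_network <- function(size, rng_seed) {
  noise <- with_seed(rng_seed, matrix(stats::runif(size * size), size, size))
  sm <- box_blur(noise, max(1L, size %/% 32L))
  q <- stats::quantile(sm, c(0.35, 0.55))
  # band-threshold produces a connected web of lines rather than blobs
  (sm > q[1L] & sm < q[2L]) * 1
}

# shared base renderer: skin background, lesion fill with anti-aliased
# border, pigment-network texture inside the lesion
render_base <- function(mask, spec, artifacts, rng_seed) {
  size <- nrow(mask)
  stopifnot(ncol(mask) == size)
  alpha <- clamp(lesion_signed_margin(spec, size), 0, 1)  # 1-px AA band
  img <- array(0, c(size, size, 3L))
  color <- spec$base_color
  skin <- artifacts$skin_tone
  if (any(color >= skin))
    stop("lesion base_color must be darker than the skin tone on all channels")
  tex <- 0
  if (spec$texture_strength > 0) {
    net <- pigment_network(size, derive_seed(rng_seed, "texture"))
    tex <- net * spec$texture_strength * 0.18
  }
  for (c in 1:3) {
    lesion_chan <- clamp(color[c] * (1 - tex), 0, 1)
    img[, , c] <- skin[c] * (1 - alpha) + lesion_chan * alpha
  }
  img
}

apply_dark_corners <- function(img, level) {
  size <- dim(img)[1L]
  g <- coord_grid(size)
  r <- sqrt((g$x - 0.5)^2 + (g$y - 0.5)^2)
  t <- clamp((r - 0.46) / 0.04, 0, 1)        # circular field of view
  for (c in 1:3) img[, , c] <- img[, , c] * (1 - t) + level * t
  img
}

apply_gel <- function(img, blur_r, rng_seed) {
  size <- dim(img)[1L]
  ctr <- with_seed(rng_seed, stats::runif(2, 0.3, 0.7))
  g <- coord_grid(size)
  w <- exp(-(((g$x - ctr[1L])^2 + (g$y - ctr[2L])^2)) / (2 * 0.12^2))
  for (c in 1:3) {
    blurred <- box_blur(img[, , c], blur_r)
    img[, , c] <- img[, , c] * (1 - w) + blurred * w
  }
  img
}

apply_ruler <- function(img) {
  size <- dim(img)[1L]
  rows <- seq(2L, max(3L, size %/% 16L))
  ticks <- seq(3L, size - 2L, by = max(4L, size %/% 12L))
  for (c in 1:3) img[rows, ticks, c] <- 0.08
  img
}

apply_depth_shading <- function(img, mask, strength, rng_seed) {
  size <- dim(img)[1L]
  ang <- with_seed(rng_seed, stats::runif(1, 0, 2 * pi))
  g <- coord_grid(size)
  proj <- cos(ang) * (g$x - 0.5) + sin(ang) * (g$y - 0.5)
  span <- max(abs(proj[mask > 0]))
  if (!is.finite(span) || span == 0) span <- 0.5
  grad <- 1 + strength * (proj / span) * (mask > 0)
  for (c in 1:3) img[, , c] <- clamp(img[, , c] * grad, 0, 1)
  img
}

apply_glare <- function(img, count, intensity, rng_seed) {
  size <- dim(img)[1L]
  centers <- with_seed(rng_seed,
                       matrix(stats::runif(2L * count, 0.25, 0.75), count, 2L))
  g <- coord_grid(size)
  sigma <- 0.035
  for (i in seq_len(count)) {
    blob <- intensity * exp(-(((g$x - centers[i, 1L])^2 +
                                 (g$y - centers[i, 2L])^2)) / (2 * sigma^2))
    for (c in 1:3) img[, , c] <- img[, , c] + blob
  }
  clamp(img, 0, 1)
}

#' Render a dermoscopic-domain lesion image
#'
#' Applies the shared base renderer (skin background, lesion fill,
#' pigment-network texture), then the dermoscope artifacts requested in
#' `artifacts`. Macroscopic-only artifacts (`glare`, `depth_shading`) are a
#' contract violation and raise an error.
#'
#' @param mask binary lesion mask from [generate_lesion_mask()].
#' @param spec the [lesion_spec()] used for the mask.
#' @param artifacts an [artifact_config()].
#' @param rng_seed integer seed driving texture and artifact placement.
#' @return an `H x W x 3` array in `[0,1]`.
#' @export
render_dermoscopic <- function(mask, spec, artifacts, rng_seed = 0L) {
  stopifnot(inherits(artifacts, "artifact_config"))
  if (isTRUE(artifacts$glare) || isTRUE(artifacts$depth_shading))
    stop("glare/depth_shading are macroscopic artifacts; not valid in the ",
         "dermoscopic renderer")
  img <- render_base(mask, spec, artifacts, rng_seed)
  if (isTRUE(artifacts$gel))
    img <- apply_gel(img, artifacts$gel_blur, derive_seed(rng_seed, "gel"))
  if (isTRUE(artifacts$ruler)) img <- apply_ruler(img)
  if (isTRUE(artifacts$dark_corners))
    img <- apply_dark_corners(img, artifacts$corner_darkness)
  img
}

#' Render a macroscopic-domain lesion image
#'
#' Same base renderer as [render_dermoscopic()]; adds the macroscopic cues:
#' optional signed depth-shading gradient across the lesion and localized
#' specular glare highlights (luminance pushed above 0.9, clipped at 1).
#' Dermoscope-only artifacts raise an error.
#'
#' @inheritParams render_dermoscopic
#' @return an `H x W x 3` array in `[0,1]`.
#' @export
render_macroscopic <- function(mask, spec, artifacts, rng_seed = 0L) {
  stopifnot(inherits(artifacts, "artifact_config"))
  if (isTRUE(artifacts$dark_corners) || isTRUE(artifacts$gel) ||
      isTRUE(artifacts$ruler))
    stop("dark_corners/gel/ruler are dermoscopic artifacts; not valid in the ",
         "macroscopic renderer")
  img <- render_base(mask, spec, artifacts, rng_seed)
  if (isTRUE(artifacts$depth_shading))
    img <- apply_depth_shading(img, mask, artifacts$depth_strength,
                               derive_seed(rng_seed, "depth"))
  if (isTRUE(artifacts$glare))
    img <- apply_glare(img, artifacts$glare_count, artifacts$glare_intensity,
                       derive_seed(rng_seed, "glare"))
  img
}

#' Configuration for synthetic dataset generation
#'
#' @param n_images images per domain.
#' @param image_size side length in pixels (>= 32).
#' @param seed root seed; identical configurations produce byte-identical
#'   datasets.
#' @param dermo_probs named artifact probabilities for the dermoscopic domain
#'   (`dark_corners`, `gel`, `ruler`).
#' @param macro_probs named artifact probabilities for the macroscopic domain
#'   (`glare`, `depth_shading`).
#' @param split_fractions named split fractions summing to 1.
#' @param dermo_skin,macro_skin background skin tones per domain; the
#'   macroscopic default is warmer (ambient rather than polarized light).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_images = 10L, image_size = 64L, seed = 1L,
                             dermo_probs = c(dark_corners = 0.7, gel = 0.2,
                                             ruler = 0.2),
                             macro_probs = c(glare = 0.7,
                                             depth_shading = 0.5),
                             split_fractions = c(train = 0.8, val = 0.1,
                                                 test = 0.1),
                             dermo_skin = c(0.85, 0.72, 0.62),
                             macro_skin = c(0.82, 0.60, 0.50)) {
  stopifnot(n_images >= 1, image_size >= 32,
            abs(sum(split_fractions) - 1) < 1e-9,
            all(dermo_probs >= 0), all(dermo_probs <= 1),
            all(macro_probs >= 0), all(macro_probs <= 1))
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 dermo_probs = dermo_probs, macro_probs = macro_probs,
                 split_fractions = split_fractions,
                 dermo_skin = dermo_skin, macro_skin = macro_skin),
            class = "synthetic_config")
}

random_lesion_spec <- function(seed) {
  with_seed(seed, {
    radius <- stats::runif(1, 0.14, 0.30)
    n_h <- sample(2:3, 1)
    amps <- stats::runif(n_h, 0, 0.4 * radius / n_h)
    phases <- stats::runif(n_h, 0, 2 * pi)
    r_base <- stats::runif(1, 0.25, 0.45)
    lesion_spec(center = stats::runif(2, 0.42, 0.58), radius = radius,
                boundary_harmonics = Map(c, amps, phases),
                base_color = c(r_base, 0.62 * r_base, 0.45 * r_base),
                texture_strength = stats::runif(1, 0.5, 1.5))
  })
}

new_sample <- function(id, domain, image, mask, split = "train",
                       artifacts = NULL) {
  structure(list(id = id, domain = domain, split = split, image = image,
                 mask = mask, artifacts = artifacts), class = "d2m_sample")
}

new_dataset <- function(samples) structure(samples, class = "d2m_dataset")

#' @export
print.d2m_dataset <- function(x, ...) {
  doms <- table(vapply(x, `[[`, "", "domain"))
  cat("<d2m_dataset>", length(x), "samples:",
      paste(names(doms), doms, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate a paired-domain synthetic dataset
#'
#' Draws `n_images` lesions per domain, renders each with its domain's
#' artifact probabilities, and tags train/val/test splits. Fully
#' deterministic in the configuration (seed included).
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `macro` and `dermo`, each a `d2m_dataset` of
#'   samples carrying `image` (`[0,1]` RGB array), `mask`, `split` and the
#'   artifact flags used.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gen_domain <- function(domain) {
    probs <- if (domain == "dermo") config$dermo_probs else config$macro_probs
    skin <- if (domain == "dermo") config$dermo_skin else config$macro_skin
    samples <- vector("list", config$n_images)
    for (i in seq_len(config$n_images)) {
      seed_i <- derive_seed(config$seed, paste0(domain, "-", i))
      spec <- random_lesion_spec(derive_seed(seed_i, "spec"))
      on_flags <- with_seed(derive_seed(seed_i, "artifacts"),
                            stats::runif(length(probs)) < probs)
      names(on_flags) <- names(probs)
      art <- if (domain == "dermo")
        artifact_config(dark_corners = on_flags[["dark_corners"]],
                        gel = on_flags[["gel"]], ruler = on_flags[["ruler"]],
                        skin_tone = skin)
      else
        artifact_config(glare = on_flags[["glare"]],
                        depth_shading = on_flags[["depth_shading"]],
                        skin_tone = skin)
      mask <- generate_lesion_mask(spec, config$image_size, seed_i)
      img <- if (domain == "dermo")
        render_dermoscopic(mask, spec, art, seed_i)
      else
        render_macroscopic(mask, spec, art, seed_i)
      samples[[i]] <- new_sample(sprintf("%s_%04d", domain, i), domain, img,
                                 mask, artifacts = as.list(on_flags))
    }
    split_dataset(new_dataset(samples), config$split_fractions,
                  seed = derive_seed(config$seed, paste0("split-", domain)))
  }
  list(macro = gen_domain("macro"), dermo = gen_domain("dermo"))
}
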