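# Preprocessing: dark-corner crop detection, cropping, resize/rescale,
# deterministic stratified splitting.

test_that("dark-corner detection matches an exhaustive box search", {
  spec <- lesion_spec(radius = 0.2)
  mask <- generate_lesion_mask(spec, 64)
  img <- render_dermoscopic(mask, spec,
                            artifact_config(dark_corners = TRUE), 3)
  box <- detect_dark_corners(img, 0.25, 0.15)
  oracle <- exhaustive_corner_box(img, 0.25, 0.15)
  expect_equal(c(box$top, box$left, box$height, box$width), oracle)
  expect_lt(box$height, 64)
  # returned box corners actually pass the threshold
  lum <- derm2macro:::luminance(img)
  ph <- floor(box$height * 0.15)
  expect_gte(mean(lum[(box$top + 1):(box$top + ph),
                      (box$left + 1):(box$left + ph)]), 0.25)
})

test_that("bright images return the whole-image box and black images are uncroppable", {
  bright <- array(0.8, c(64, 64, 3))
  box <- detect_dark_corners(bright, 0.25, 0.15)
  expect_equal(c(box$top, box$left, box$height, box$width), c(0, 0, 64, 64))
  expect_error(detect_dark_corners(array(0, c(64, 64, 3))), "uncroppable")
  expect_error(detect_dark_corners(array(0.5, c(48, 48, 3))), "64")
})

test_that("crop slices image and mask identically", {
  set.seed(4)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(crop(img, crop_box(0, 0, 64, 64)), img)
  # centred half-size box keeps a centred lesion intact
  spec <- lesion_spec(radius = 0.12)
  mask <- generate_lesion_mask(spec, 64)
  out <- crop(img, crop_box(16, 16, 32, 32), mask)
  expect_identical(sum(out$mask), sum(mask))
  # arbitrary box equals index slicing
  box <- crop_box(5, 9, 40, 33)
  expect_identical(crop(img, box), img[6:45, 10:42, , drop = FALSE])
  expect_error(crop(img, crop_box(30, 30, 40, 40)), "bounds")
  # mask foreground can only shrink
  out2 <- crop(img, crop_box(0, 30, 64, 34), mask)
  expect_lte(sum(out2$mask), sum(mask))
})

test_that("resize_and_scale maps ranges and interpolates bilinearly", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  same <- resize_and_scale(img, 64)
  expect_identical(same, img)
  ones <- array(1, c(64, 64, 3))
  expect_equal(resize_and_scale(ones, 64, "sym"),
               array(1, c(64, 64, 3)))
  expect_equal(range(resize_and_scale(img, 32, "sym")) >= -1, c(TRUE, TRUE))
  down <- resize_and_scale(img, 32)
  expect_equal(down, bilinear_oracle(img, 32, 32), tolerance = 1e-12)
  expect_error(resize_and_scale(img, 0), "positive")
})

test_that("split_dataset matches requested fractions exactly and is a permutation", {
  mk <- function(n, label = NULL) {
    derm2macro:::new_dataset(lapply(seq_len(n), function(i) {
      s <- derm2macro:::new_sample(paste0("s", i), "macro",
                                   array(0, c(32, 32, 3)), NULL)
      if (!is.null(label)) s$label <- label[i]
      s
    }))
  }
  tab <- function(ds) table(vapply(ds, `[[`, "", "split"))
  t1 <- tab(split_dataset(mk(100), c(train = 0.9, val = 0.1), seed = 1))
  expect_equal(unclass(t1)[c("train", "val")], c(train = 90, val = 10),
               ignore_attr = TRUE)
  t2 <- tab(split_dataset(mk(80), c(train = 0.5, test = 0.5), seed = 1))
  expect_equal(unclass(t2)[c("train", "test")], c(train = 40, test = 40),
               ignore_attr = TRUE)
  # stratified 60 benign / 40 malignant at 80/20
  lab <- c(rep("benign", 60), rep("malignant", 40))
  ds <- split_dataset(mk(100, lab), c(train = 0.8, test = 0.2),
                      stratify_key = "label", seed = 2)
  splits <- vapply(ds, `[[`, "", "split")
  labs <- vapply(ds, `[[`, "", "label")
  expect_equal(sum(splits == "train" & labs == "benign"), 48)
  expect_equal(sum(splits == "test" & labs == "benign"), 12)
  expect_equal(sum(splits == "train" & labs == "malignant"), 32)
  expect_equal(sum(splits == "test" & labs == "malignant"), 8)
  # permutation: every sample tagged exactly once, ids preserved
  expect_setequal(vapply(ds, `[[`, "", "id"), paste0("s", 1:100))
  # determinism
  ds2 <- split_dataset(mk(100, lab), c(train = 0.8, test = 0.2),
                       stratify_key = "label", seed = 2)
  expect_identical(vapply(ds2, `[[`, "", "split"), splits)
  expect_warning(split_dataset(mk(2), c(a = 0.4, b = 0.3, c = 0.3)),
                 "best-effort")
})

test_that("crop-then-resize keeps mask and image foreground consistent", {
  spec <- lesion_spec(radius = 0.2)
  mask <- generate_lesion_mask(spec, 64)
  img <- render_dermoscopic(mask, spec,
                            artifact_config(dark_corners = TRUE), 5)
  box <- detect_dark_corners(img)
  cr <- crop(img, box, mask)
  rs_mask <- bilinear_resize(cr$mask + 0, 32, 32)
  oracle_mask <- bilinear_oracle(array(cr$mask, c(dim(cr$mask), 1)), 32, 32)[, , 1]
  expect_equal(mean(rs_mask), mean(oracle_mask), tolerance = 1e-12)
  expect_equal(abs(mean(rs_mask >= 0.5) - mean(cr$mask)) < 0.05, TRUE)
})
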