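# PNG image / mask I/O and manifest-driven dataset reading and writing.

#' Write an RGB image as 8-bit PNG
#' @param image `H x W x 3` array in `[0,1]` (clamped before quantisation).
#' @param path output file path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 1), path)
  invisible(path)
}

#' Write a binary mask as 8-bit single-channel PNG (0/255)
#' @param mask binary `H x W` matrix.
#' @param path output file path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read an image PNG/JPEG-decoded array as RGB in `[0,1]`
#' @param path file path.
#' @return `H x W x 3` array.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]   # drop alpha if present
}

#' Read a mask PNG as a binary matrix
#' @param path file path.
#' @return `H x W` integer matrix with values 0/1.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  (m > 0.5) * 1L
}

#' Write a dataset as PNG images, masks and a manifest CSV
#'
#' Layout: `<dir>/images/<id>.png`, `<dir>/masks/<id>.png`, and
#' `<dir>/manifest.csv` with columns id, domain, split, image_path,
#' mask_path, artifact flags and an md5 checksum per image.
#'
#' @param dataset a `d2m_dataset` (images in `[0,1]`).
#' @param dir output directory (created if missing).
#' @return the manifest data frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset, function(s) {
    img_path <- file.path(dir, "images", paste0(s$id, ".png"))
    write_image_png(s$image, img_path)
    mask_path <- NA_character_
    if (!is.null(s$mask)) {
      mask_path <- file.path(dir, "masks", paste0(s$id, ".png"))
      write_mask_png(s$mask, mask_path)
    }
    flags <- if (is.null(s$artifacts)) list()
    else lapply(s$artifacts, function(x) as.integer(isTRUE(x) || x == 1))
    c(list(id = s$id, domain = s$domain, split = s$split,
           image_path = basename(img_path),
           mask_path = if (is.na(mask_path)) "" else basename(mask_path),
           md5 = unname(tools::md5sum(img_path))),
      flags)
  })
  cols <- unique(unlist(lapply(rows, names)))
  manifest <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(c(r, stats::setNames(as.list(rep(NA, length(setdiff(cols,
      names(r))))), setdiff(cols, names(r)))))[, cols]
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return a `d2m_dataset`.
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    mask <- if (nzchar(row$mask_path %||% ""))
      read_mask_png(file.path(dir, "masks", row$mask_path)) else NULL
    new_sample(row$id, row$domain,
               read_image_png(file.path(dir, "images", row$image_path)),
               mask, split = row$split)
  })
  new_dataset(samples)
}
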