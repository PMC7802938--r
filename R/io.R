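#' Read an RGB image
#'
#' Reads PNG (always available), TIFF or JPEG, returning an H x W x 3
#' array of intensities in \[0, 1\] (scaled by the file's sample depth).
#' Grayscale images are replicated to 3 channels and an alpha channel is
#' dropped, each with a warning.
#'
#' @param path image file; format chosen by extension.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required to read TIFF files")
      tiff::readTIFF(path)  # scaled to [0,1] by sample depth
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the jpeg package is required to read JPEG files")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (is.matrix(x)) warning("grayscale image replicated to 3 channels")
  if (!is.matrix(x) && dim(x)[3] == 1L)
    warning("grayscale image replicated to 3 channels")
  suppressWarnings(as_rgb_array(x, what = path))
}

#' Read a binary mask
#'
#' Reads a single-channel PNG and binarizes it at 128 (8-bit scale): pixel
#' values >= 128 become 1. Multi-channel mask files use their first
#' channel.
#'
#' @param path PNG file.
#' @return H x W integer matrix in \{0, 1\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1]
  m <- matrix(0L, nrow(x), ncol(x))
  m[round(x * 255) >= 128] <- 1L
  m
}

#' Write a binary mask as a \{0, 255\} PNG
#'
#' @param mask H x W matrix in \{0, 1\}.
#' @param path output PNG path.
#' @return the path, invisibly; `read_mask(write_mask(m)) == m`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% c(0, 1)))
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write an RGB image as PNG
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output PNG path.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Load an annotated dataset from the directory convention
#'
#' Expects `dir/images/*.png` and `dir/masks/*.png` with matching stems
#' (the layout written by [generate_corpus()]).
#'
#' @param dir dataset directory.
#' @return list of [annotated_pair()].
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  if (length(imgs) == 0) stop("no images under ", file.path(dir, "images"))
  lapply(imgs, function(f) {
    stem <- tools::file_path_sans_ext(basename(f))
    mf <- file.path(dir, "masks", paste0(stem, ".png"))
    if (!file.exists(mf)) stop("no mask matching image stem: ", stem)
    annotated_pair(read_image(f), read_mask(mf), id = stem)
  })
}
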