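#' Segment an image of arbitrary size
#'
#' Applies the network to an image larger (or smaller) than its input tile
#' by sliding-window tiling with the stated overlap. Probabilities are
#' averaged per pixel wherever tiles overlap; borders are reflection-padded
#' so every pixel is covered, and images smaller than one tile are padded
#' up, processed, and cropped back. The averaged probability map is then
#' thresholded to a binary mask.
#'
#' @param network a trained `segmentation_network`.
#' @param image H x W x 3 array in \[0, 1\] of any size.
#' @param overlap overlap in pixels between adjacent tiles (default 32;
#'   must be smaller than the tile size).
#' @param threshold probability threshold in (0, 1) for foreground
#'   (default 0.5); pixels with probability >= threshold become 1.
#' @param return_prob also return the averaged probability map.
#' @return integer H x W mask in \{0, 1\}; if `return_prob`, a list with
#'   `mask` and `prob`.
#' @export
segment_image <- function(network, image, overlap = 32, threshold = 0.5,
                          return_prob = FALSE) {
  stopifnot(inherits(network, "segmentation_network"))
  cfg <- network$config
  tile_h <- cfg$input_height; tile_w <- cfg$input_width
  if (overlap >= min(tile_h, tile_w)) stop("overlap must be < tile size")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  image <- as_rgb_array(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  # reflection-pad up to at least one tile (iterated if the image is less
  # than half a tile in either dimension)
  padded <- image
  while (dim(padded)[1] < tile_h)
    padded <- pad_reflect(padded, min(tile_h - dim(padded)[1],
                                      dim(padded)[1] - 1), 0)
  while (dim(padded)[2] < tile_w)
    padded <- pad_reflect(padded, 0, min(tile_w - dim(padded)[2],
                                         dim(padded)[2] - 1))
  Hp <- dim(padded)[1]; Wp <- dim(padded)[2]
  stride_h <- tile_h - overlap
  stride_w <- tile_w - overlap
  starts <- function(total, tile, stride) {
    s <- seq(1, max(1, total - tile + 1), by = stride)
    unique(c(s, total - tile + 1))
  }
  acc <- matrix(0, Hp, Wp)
  cnt <- matrix(0, Hp, Wp)
  for (i0 in starts(Hp, tile_h, stride_h)) {
    for (j0 in starts(Wp, tile_w, stride_w)) {
      ri <- i0:(i0 + tile_h - 1)
      ci <- j0:(j0 + tile_w - 1)
      p <- segment_tile(network, padded[ri, ci, , drop = FALSE])
      acc[ri, ci] <- acc[ri, ci] + p
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  }
  prob <- (acc / cnt)[seq_len(H), seq_len(W), drop = FALSE]
  mask <- matrix(0L, H, W)
  mask[prob >= threshold] <- 1L
  if (return_prob) list(mask = mask, prob = prob) else mask
}
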