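#' Construct an annotated image/mask pair
#'
#' The atomic training and evaluation unit: an RGB image in \[0, 1\] and its
#' aligned binary ground-truth mask.
#'
#' @param image H x W x 3 array, intensities in \[0, 1\].
#' @param mask H x W integer matrix with values in \{0, 1\}.
#' @param id identifier string.
#' @return object of class `annotated_pair`.
#' @export
annotated_pair <- function(image, mask, id = "pair") {
  image <- as_rgb_array(image)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask dimensions differ")
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  structure(list(image = image, mask = mask, id = id),
            class = "annotated_pair")
}

# geometric helpers operating jointly on image (H x W x C) and mask (H x W)
flip_h <- function(x) {
  if (is.matrix(x)) x[, rev(seq_len(ncol(x))), drop = FALSE]
  else x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
}

# counter-clockwise quarter-turn rotations, q in 1:3
rot_q <- function(x, q) {
  rot1 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  apply_one <- function(m) { for (i in seq_len(q)) m <- rot1(m); m }
  if (is.matrix(x)) apply_one(x)
  else {
    sl <- lapply(seq_len(dim(x)[3]), function(c) apply_one(x[, , c]))
    array(unlist(sl), c(dim(sl[[1]]), dim(x)[3]))
  }
}

shift_xy <- function(x, dr, dc) {
  one <- function(m) {
    out <- m * 0
    H <- nrow(m); W <- ncol(m)
    sr <- max(1, 1 + dr):min(H, H + dr)
    sc <- max(1, 1 + dc):min(W, W + dc)
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
    out
  }
  if (is.matrix(x)) one(x)
  else {
    sl <- lapply(seq_len(dim(x)[3]), function(c) one(x[, , c]))
    array(unlist(sl), dim(x))
  }
}

#' Expand an annotated dataset fourfold
#'
#' Implements the fixed expansion scheme used to grow the training set:
#' each input pair yields exactly four pairs -- the original plus one
#' mirrored, one translated and one rotated variant -- with the identical
#' geometric transform applied to image and mask, so 128 annotated pairs
#' become 512 training pairs.
#'
#' @param pairs list of [annotated_pair()] objects.
#' @param max_shift maximum translation as a fraction of each dimension
#'   (default 0.1); offsets are drawn uniformly and vacated pixels are
#'   zero-filled.
#' @param seed RNG seed for the translation offsets and rotation choices.
#' @return list of `4 * length(pairs)` annotated pairs.
#' @export
expand_dataset <- function(pairs, max_shift = 0.1, seed = 1) {
  if (length(pairs) == 0) stop("empty input dataset")
  with_local_seed(seed, {
    out <- vector("list", 4L * length(pairs))
    j <- 0L
    for (p in pairs) {
      stopifnot(inherits(p, "annotated_pair"))
      H <- nrow(p$mask); W <- ncol(p$mask)
      dr <- sample(seq(-round(max_shift * H), round(max_shift * H)), 1)
      dc <- sample(seq(-round(max_shift * W), round(max_shift * W)), 1)
      q <- sample(1:3, 1)  # 90, 180 or 270 degrees
      out[[j + 1L]] <- p
      out[[j + 2L]] <- annotated_pair(flip_h(p$image), flip_h(p$mask),
                                      paste0(p$id, "_mirror"))
      out[[j + 3L]] <- annotated_pair(shift_xy(p$image, dr, dc),
                                      shift_xy(p$mask, dr, dc),
                                      paste0(p$id, "_shift"))
      out[[j + 4L]] <- annotated_pair(rot_q(p$image, q), rot_q(p$mask, q),
                                      paste0(p$id, "_rot", 90 * q))
      j <- j + 4L
    }
    out
  })
}

#' Random elastic deformation of an annotated pair
#'
#' Draws a `grid x grid` field of independent 2-D displacements from
#' `Normal(0, sigma^2)` (pixels), interpolates it smoothly (cubic splines)
#' to full resolution, and warps image and mask with the same field --
#' bilinear interpolation for the image, nearest neighbour for the mask so
#' binarity is preserved. The same seed always yields the same deformation.
#'
#' @param pair an [annotated_pair()].
#' @param grid nodes per side of the coarse displacement grid (default 3).
#' @param sigma displacement standard deviation in pixels (default 10);
#'   0 returns the input unchanged.
#' @param seed RNG seed.
#' @return deformed `annotated_pair`.
#' @export
elastic_deform <- function(pair, grid = 3, sigma = 10, seed = 1) {
  stopifnot(inherits(pair, "annotated_pair"), grid >= 2, sigma >= 0)
  if (sigma == 0) return(pair)
  H <- nrow(pair$mask); W <- ncol(pair$mask)
  with_local_seed(seed, {
    dr <- upsample_grid(matrix(rnorm(grid^2, 0, sigma), grid, grid), H, W)
    dc <- upsample_grid(matrix(rnorm(grid^2, 0, sigma), grid, grid), H, W)
    img <- cpp_warp_bilinear(pair$image, dr, dc)
    msk <- cpp_warp_nearest(pair$mask, dr, dc)
    annotated_pair(img, msk, paste0(pair$id, "_elastic"))
  })
}

#' Train a segmentation network
#'
#' Adam optimization with batch size 1: each epoch draws
#' `steps_per_epoch` training pairs with replacement, applies an on-the-fly
#' elastic deformation to each, and takes one gradient step on the binary
#' cross-entropy. After every epoch the validation loss is computed (no
#' dropout, no deformation); training stops when it has not improved by at
#' least `min_delta` for `patience_epochs` epochs, or at `max_epochs`. The
#' returned network carries the parameters of the best validation epoch.
#'
#' @param network a [build_network()] object.
#' @param train_set,val_set non-empty lists of [annotated_pair()]s matching
#'   the network input size.
#' @param config a [training_config()].
#' @param verbose print a one-line summary per epoch.
#' @return list with elements `network` (best parameters) and `history`
#'   (data.frame: epoch, train_loss, val_loss).
#' @export
train <- function(network, train_set, val_set, config = training_config(),
                  verbose = FALSE) {
  stopifnot(inherits(network, "segmentation_network"),
            inherits(config, "training_config"),
            length(train_set) > 0, length(val_set) > 0)
  set.seed(config$seed)
  state <- adam_init(network$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- network$params
  wait <- 0L
  step_id <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    tr_losses <- numeric(config$steps_per_epoch)
    for (s in seq_len(config$steps_per_epoch)) {
      step_id <- step_id + 1L
      p <- train_set[[sample.int(length(train_set), 1)]]
      if (config$elastic_sigma > 0)
        p <- elastic_deform(p, config$elastic_grid, config$elastic_sigma,
                            seed = derive_seed(config$seed, step_id))
      fw <- net_forward(network, p$image, train = TRUE)
      lg <- bce_with_logits(fw$logits, p$mask)
      if (!is.finite(lg$loss))
        stop(sprintf("non-finite training loss at epoch %d, step %d",
                     epoch, s))
      tr_losses[s] <- lg$loss
      grads <- net_backward(network, fw$cache, lg$grad)
      upd <- adam_step(network$params, grads, state, config$learning_rate)
      network$params <- upd$params
      state <- upd$state
    }
    val_loss <- mean(vapply(val_set, function(v) {
      fw <- net_forward(network, v$image, train = FALSE, keep_cache = FALSE)
      bce_with_logits(fw$logits, v$mask)$loss
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(tr_losses),
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(tr_losses), val_loss))
    if (val_loss < best_val - config$min_delta) {
      best_val <- val_loss
      best_params <- network$params
      wait <- 0L
    } else wait <- wait + 1L
    if (wait >= config$patience_epochs) break
  }
  network$params <- best_params
  list(network = network, history = history)
}

#' Write a training-history CSV
#'
#' @param history the `history` data.frame returned by [train()].
#' @param path CSV file to write (columns epoch, train_loss, val_loss).
#' @export
write_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}
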