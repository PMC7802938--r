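#' Network architecture configuration
#'
#' Describes the compact three-level encoder-decoder: per-level encoder
#' filter counts, the two bottleneck convolutions, and the post-fusion
#' decoder convolutions. When `bottleneck_filters` or `up_filters` are not
#' given they are derived from `down_filters` by the same pattern as the
#' reference architecture (bottleneck `2f_n, f_n`; decoder level k fuses the
#' matching encoder map and reduces through `f_{n+1-k}, f_{n-k}` filters),
#' so a reduced network is obtained by supplying smaller `down_filters`
#' alone.
#'
#' @param input_height,input_width input tile size in pixels (default 256);
#'   must be divisible by `2^length(down_filters)`.
#' @param input_channels number of input channels (3 for RGB).
#' @param down_filters convolution filter counts of the downsampling
#'   modules, one per level (default `c(32, 64, 128)`).
#' @param bottleneck_filters filter counts of the two bottleneck
#'   convolutions (default derived: `c(256, 128)`).
#' @param up_filters list of filter-count vectors for the convolutions of
#'   each upsampling module (default derived:
#'   `list(c(128, 64), c(64, 32), 32)`).
#' @param kernel_size convolution kernel size (3).
#' @param pool_size pooling window (2).
#' @param leaky_slope negative-side slope of the Leaky ReLU activation.
#' @param dropout_rate dropout probability applied after the bottleneck
#'   convolutions during training (default 0.5).
#' @param output_channels channels of the probability output (1).
#' @param final_kernel kernel size of the output convolution; 1 by default,
#'   3 as an alternative (identical output shape under same padding).
#' @param upsampling `"tconv"` (2x2 stride-2 transposed convolution, the
#'   default) or reserved for future interpolation variants.
#' @return object of class `network_config`.
#' @examples
#' cfg <- network_config()
#' network_shapes(cfg)
#' small <- network_config(input_height = 64, input_width = 64,
#'                         down_filters = c(8, 16, 32))
#' @export
network_config <- function(input_height = 256, input_width = 256,
                           input_channels = 3,
                           down_filters = c(32, 64, 128),
                           bottleneck_filters = NULL,
                           up_filters = NULL,
                           kernel_size = 3, pool_size = 2,
                           leaky_slope = 0.01, dropout_rate = 0.5,
                           output_channels = 1, final_kernel = 1,
                           upsampling = "tconv") {
  n <- length(down_filters)
  if (n < 1) stop("down_filters must be non-empty")
  if (is.null(bottleneck_filters))
    bottleneck_filters <- c(2 * down_filters[n], down_filters[n])
  if (is.null(up_filters))
    up_filters <- lapply(seq_len(n), function(k) {
      if (k < n) c(down_filters[n + 1 - k], down_filters[n - k])
      else down_filters[1]
    })
  if (length(up_filters) != n)
    stop("up_filters must have one entry per downsampling module")
  if (input_height %% 2^n != 0 || input_width %% 2^n != 0)
    stop("input size must be divisible by 2^", n,
         " (number of downsampling modules)")
  if (kernel_size %% 2 != 1 || final_kernel %% 2 != 1)
    stop("kernel sizes must be odd (same padding)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0,1)")
  if (leaky_slope < 0) stop("leaky_slope must be non-negative")
  structure(list(
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    input_channels = as.integer(input_channels),
    down_filters = as.integer(down_filters),
    bottleneck_filters = as.integer(bottleneck_filters),
    up_filters = lapply(up_filters, as.integer),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    leaky_slope = leaky_slope,
    dropout_rate = dropout_rate,
    output_channels = as.integer(output_channels),
    final_kernel = as.integer(final_kernel),
    upsampling = upsampling
  ), class = "network_config")
}

#' Per-module shape audit of the architecture
#'
#' Returns the module-level layer table of the network implied by a
#' configuration: each downsampling module, the bottleneck convolution
#' module, each upsampling module, and the final 1x1 convolution, with
#' input shape, convolution filters, and output shape. With the default
#' configuration this reproduces the eight rows of the reference layer
#' table.
#'
#' @param config a [network_config()].
#' @return data.frame with columns `layer`, `input`, `filters`, `output`.
#' @export
network_shapes <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n <- length(config$down_filters)
  H <- config$input_height; W <- config$input_width
  sh <- function(h, w, c) sprintf("%dx%dx%d", h, w, c)
  k <- config$kernel_size
  rows <- list()
  cin <- config$input_channels
  for (i in seq_len(n)) {
    f <- config$down_filters[i]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("Downsampling module %d", i),
      input = sh(H, W, cin),
      filters = sprintf("%dx%dx%d", k, k, f),
      output = sh(H / 2, W / 2, f))
    H <- H / 2; W <- W / 2; cin <- f
  }
  bf <- config$bottleneck_filters
  rows[[length(rows) + 1]] <- data.frame(
    layer = "Convolution module",
    input = sh(H, W, cin),
    filters = paste(sprintf("%dx%dx%d", k, k, bf), collapse = ", "),
    output = sh(H, W, bf[length(bf)]))
  cin <- bf[length(bf)]
  for (i in seq_len(n)) {
    uf <- config$up_filters[[i]]
    rows[[length(rows) + 1]] <- data.frame(
      layer = sprintf("Upsampling module %d", i),
      input = sh(H, W, cin),
      filters = paste(sprintf("%dx%dx%d", k, k, uf), collapse = ", "),
      output = sh(H * 2, W * 2, uf[length(uf)]))
    H <- H * 2; W <- W * 2; cin <- uf[length(uf)]
  }
  fk <- config$final_kernel
  rows[[length(rows) + 1]] <- data.frame(
    layer = sprintf("Convolution %dx%d", fk, fk),
    input = sh(H, W, cin),
    filters = sprintf("%dx%dx%d", fk, fk, config$output_channels),
    output = sh(H, W, config$output_channels))
  do.call(rbind, rows)
}

#' Training hyper-parameters
#'
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param batch_size images per gradient step (1, as in the reference
#'   protocol).
#' @param steps_per_epoch training pairs drawn (with replacement) per epoch
#'   (default 200).
#' @param max_epochs hard cap on epochs (default 500).
#' @param patience_epochs epochs without validation improvement before
#'   early stopping (default 20).
#' @param min_delta minimum decrease in validation loss that counts as an
#'   improvement (default 1e-4).
#' @param elastic_grid side of the coarse displacement grid of the elastic
#'   augmenter (default 3).
#' @param elastic_sigma standard deviation, in pixels, of the random grid
#'   displacements (default 10); 0 disables deformation.
#' @param seed RNG seed controlling sampling, dropout and deformation.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 1,
                            steps_per_epoch = 200, max_epochs = 500,
                            patience_epochs = 20, min_delta = 1e-4,
                            elastic_grid = 3, elastic_sigma = 10,
                            seed = 1) {
  stopifnot(batch_size >= 1, steps_per_epoch >= 1, max_epochs >= 1,
            patience_epochs >= 1, elastic_grid >= 2, elastic_sigma >= 0,
            learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 max_epochs = as.integer(max_epochs),
                 patience_epochs = as.integer(patience_epochs),
                 min_delta = min_delta,
                 elastic_grid = as.integer(elastic_grid),
                 elastic_sigma = elastic_sigma,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Serialize a configuration to YAML
#'
#' @param config a `network_config`, `training_config` or plain named list.
#' @param path file to write.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$.class <- class(config)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path YAML file.
#' @return the configuration with its original class; fields round-trip
#'   unchanged.
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class %||% "list"
  obj$.class <- NULL
  if (cls == "network_config") {
    do.call(network_config, obj)
  } else if (cls == "training_config") {
    do.call(training_config, obj)
  } else obj
}
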