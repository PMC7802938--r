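#' Build a segmentation network
#'
#' Instantiates the encoder-decoder: per downsampling module a 3x3
#' same-padded convolution (Leaky ReLU) followed by 2x2 max pooling; a
#' bottleneck of two 3x3 convolutions with dropout; per upsampling module a
#' 2x2 stride-2 transposed convolution whose output is fused
#' (channel-concatenated) with the matching encoder feature map and reduced
#' through the configured 3x3 convolutions; and a final 1x1 convolution
#' whose sigmoid yields the foreground probability map. Weights use He
#' initialization.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return object of class `segmentation_network`.
#' @export
build_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  n <- length(config$down_filters)
  k <- config$kernel_size
  params <- list()
  with_local_seed(seed, {
    he_conv <- function(cin, f, k) {
      fan_in <- k * k * cin
      list(W = matrix(rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f),
           b = numeric(f), k = as.integer(k))
    }
    he_tconv <- function(cin, f) {
      list(W = matrix(rnorm(cin * 4 * f, sd = sqrt(2 / cin)), cin, 4 * f),
           b = numeric(f))
    }
    cin <- config$input_channels
    for (i in seq_len(n)) {
      params[[paste0("down", i)]] <- he_conv(cin, config$down_filters[i], k)
      cin <- config$down_filters[i]
    }
    for (j in seq_along(config$bottleneck_filters)) {
      params[[paste0("bn", j)]] <- he_conv(cin, config$bottleneck_filters[j], k)
      cin <- config$bottleneck_filters[j]
    }
    for (i in seq_len(n)) {
      # transposed conv keeps the channel count; fusion then doubles it
      params[[paste0("up", i, "_t")]] <- he_tconv(cin, cin)
      skip_c <- config$down_filters[n + 1 - i]
      cin <- cin + skip_c
      for (j in seq_along(config$up_filters[[i]])) {
        params[[paste0("up", i, "_c", j)]] <-
          he_conv(cin, config$up_filters[[i]][j], k)
        cin <- config$up_filters[[i]][j]
      }
    }
    params[["out"]] <- he_conv(cin, config$output_channels,
                               config$final_kernel)
  })
  structure(list(config = config, params = params, plan = net_plan(config)),
            class = "segmentation_network")
}

# linearized execution plan: a sequence of primitive steps; skip connections
# are realized by save_skip (encoder side) and concat (decoder side)
net_plan <- function(config) {
  n <- length(config$down_filters)
  steps <- list()
  add <- function(...) steps[[length(steps) + 1]] <<- list(...)
  for (i in seq_len(n)) {
    add(op = "conv", name = paste0("down", i), act = TRUE)
    add(op = "save_skip", id = i)
    add(op = "pool")
  }
  for (j in seq_along(config$bottleneck_filters))
    add(op = "conv", name = paste0("bn", j), act = TRUE)
  add(op = "dropout")
  for (i in seq_len(n)) {
    add(op = "tconv", name = paste0("up", i, "_t"))
    add(op = "concat", id = n + 1 - i)
    for (j in seq_along(config$up_filters[[i]]))
      add(op = "conv", name = paste0("up", i, "_c", j), act = TRUE)
  }
  add(op = "conv", name = "out", act = FALSE)
  steps
}

# forward pass; returns pre-sigmoid logits plus, when train = TRUE or
# keep_cache = TRUE, the per-step cache needed by net_backward
net_forward <- function(net, x, train = FALSE, keep_cache = train) {
  cfg <- net$config
  d <- dim(x)
  if (length(d) != 3 || d[1] != cfg$input_height || d[2] != cfg$input_width ||
      d[3] != cfg$input_channels)
    stop(sprintf("input size mismatch: expected %dx%dx%d, got %s",
                 cfg$input_height, cfg$input_width, cfg$input_channels,
                 paste(d, collapse = "x")))
  slope <- cfg$leaky_slope
  skips <- list()
  cache <- if (keep_cache) vector("list", length(net$plan)) else NULL
  h <- x
  for (s in seq_along(net$plan)) {
    st <- net$plan[[s]]
    if (st$op == "conv") {
      p <- net$params[[st$name]]
      if (keep_cache) cache[[s]] <- list(x = h)
      z <- cpp_conv_forward(h, p$W, p$b, p$k)
      if (st$act) {
        if (keep_cache) cache[[s]]$z <- z
        h <- leaky_relu(z, slope)
      } else h <- z
    } else if (st$op == "pool") {
      pr <- cpp_maxpool_forward(h)
      if (keep_cache) cache[[s]] <- list(idx = pr$idx)
      h <- pr$out
    } else if (st$op == "save_skip") {
      skips[[st$id]] <- h
    } else if (st$op == "dropout") {
      if (train && cfg$dropout_rate > 0) {
        keep <- array(runif(length(h)) >= cfg$dropout_rate, dim(h))
        m <- keep / (1 - cfg$dropout_rate)
        if (keep_cache) cache[[s]] <- list(mask = m)
        h <- h * m
      }
    } else if (st$op == "tconv") {
      p <- net$params[[st$name]]
      if (keep_cache) cache[[s]] <- list(x = h)
      z <- cpp_tconv_forward(h, p$W, p$b)
      if (keep_cache) cache[[s]]$z <- z
      h <- leaky_relu(z, slope)
    } else if (st$op == "concat") {
      if (keep_cache) cache[[s]] <- list(c1 = dim(h)[3])
      h <- abind3(h, skips[[st$id]])
    }
  }
  list(logits = h, cache = cache)
}

# reverse pass over the plan; returns the per-parameter gradients
net_backward <- function(net, cache, glogits) {
  cfg <- net$config
  slope <- cfg$leaky_slope
  g <- glogits
  gskips <- list()
  grads <- list()
  for (s in rev(seq_along(net$plan))) {
    st <- net$plan[[s]]
    if (st$op == "conv") {
      p <- net$params[[st$name]]
      if (st$act) g <- g * leaky_relu_grad(cache[[s]]$z, slope)
      r <- cpp_conv_backward(cache[[s]]$x, p$W, g, p$k)
      grads[[st$name]] <- list(W = r$gW, b = as.numeric(r$gb))
      g <- r$gx
    } else if (st$op == "pool") {
      g <- cpp_maxpool_backward(g, cache[[s]]$idx)
    } else if (st$op == "save_skip") {
      gs <- gskips[[as.character(st$id)]]
      if (!is.null(gs)) g <- g + gs
    } else if (st$op == "dropout") {
      if (!is.null(cache[[s]]$mask)) g <- g * cache[[s]]$mask
    } else if (st$op == "tconv") {
      p <- net$params[[st$name]]
      g <- g * leaky_relu_grad(cache[[s]]$z, slope)
      r <- cpp_tconv_backward(cache[[s]]$x, p$W, g)
      grads[[st$name]] <- list(W = r$gW, b = as.numeric(r$gb))
      g <- r$gx
    } else if (st$op == "concat") {
      c1 <- cache[[s]]$c1
      ctot <- dim(g)[3]
      gskips[[as.character(st$id)]] <- g[, , (c1 + 1):ctot, drop = FALSE]
      g <- g[, , seq_len(c1), drop = FALSE]
    }
  }
  grads
}

# combined BCE-with-logits loss and its gradient wrt the logits
bce_with_logits <- function(logits, y, eps = 1e-7) {
  p <- sigmoid(logits)
  loss <- binary_cross_entropy(y, p, eps)
  list(loss = loss, grad = (p - array(y, dim(p))) / length(p), prob = p)
}

#' Forward pass on a single tile
#'
#' Runs the network on one image of exactly the configured input size and
#' returns the foreground probability map, without thresholding.
#'
#' @param network a trained [build_network()] object.
#' @param image H x W x 3 array with intensities in \[0, 1\], matching the
#'   network input size.
#' @return H x W matrix of probabilities in (0, 1).
#' @export
segment_tile <- function(network, image) {
  stopifnot(inherits(network, "segmentation_network"))
  out <- net_forward(network, image, train = FALSE, keep_cache = FALSE)
  sigmoid(out$logits[, , 1])
}

#' @export
print.segmentation_network <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                   numeric(1)))
  cat(sprintf("segmentation network: %dx%dx%d input, %d levels, %s params\n",
              cfg$input_height, cfg$input_width, cfg$input_channels,
              length(cfg$down_filters), format(np, big.mark = ",")))
  print(network_shapes(cfg), row.names = FALSE)
  invisible(x)
}

#' Save / load a network checkpoint
#'
#' Checkpoints are RDS files holding the trainable parameters with the
#' architecture configuration embedded, so a checkpoint alone is sufficient
#' to rebuild the network.
#'
#' @param network a `segmentation_network`.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(network, path) {
  stopifnot(inherits(network, "segmentation_network"))
  saveRDS(list(config = unclass(network$config), params = network$params),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `segmentation_network`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(network_config, obj$config)
  net <- build_network(cfg, seed = 1)
  net$params <- obj$params
  net
}

# Adam optimizer over the named parameter list
adam_init <- function(params) {
  zero_like <- function(p) lapply(p[intersect(names(p), c("W", "b"))],
                                  function(x) x * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (slot in names(grads[[nm]])) {
      g <- grads[[nm]][[slot]]
      m <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      state$m[[nm]][[slot]] <- m
      state$v[[nm]][[slot]] <- v
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
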