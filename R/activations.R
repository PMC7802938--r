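#' Leaky rectified linear activation
#'
#' Elementwise activation used throughout the hidden layers of the network:
#' the identity for non-negative inputs and a small linear leak `slope * x`
#' for negative inputs, so that units keep a gradient when inactive.
#'
#' @param x numeric vector, matrix or array.
#' @param slope non-negative leak coefficient for negative inputs
#'   (default 0.01).
#' @return object of the same shape as `x`.
#' @examples
#' leaky_relu(c(-10, 0, 5))
#' @export
leaky_relu <- function(x, slope = 0.01) {
  if (slope < 0) stop("slope must be non-negative")
  out <- x
  neg <- x < 0
  out[neg] <- slope * x[neg]
  out
}

# derivative of leaky_relu wrt its pre-activation
leaky_relu_grad <- function(z, slope) {
  d <- array(1, dim(z) %||% length(z))
  d[z < 0] <- slope
  d
}

#' Logistic sigmoid
#'
#' Maps a real number to the open interval (0, 1); used on the output layer
#' to turn logits into foreground probabilities. Numerically stable for
#' arguments of large magnitude (no overflow up to |x| ~ 1e3 and beyond).
#'
#' @param x numeric vector, matrix or array.
#' @return values in (0, 1), same shape as `x`.
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1000)   # ~1, no overflow
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Binary cross-entropy loss
#'
#' Mean pixelwise cross-entropy between a binary target and predicted
#' foreground probabilities, the training loss of the segmentation network.
#' Predictions are clipped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param y_true binary target (values in \{0, 1\}), any shape.
#' @param y_pred predicted probabilities, same shape.
#' @param eps clipping constant guarding `log(0)` (default 1e-7).
#' @return non-negative scalar; 0 iff the prediction equals the target (up
#'   to clipping).
#' @examples
#' binary_cross_entropy(1, 0.5)  # log 2
#' @export
binary_cross_entropy <- function(y_true, y_pred, eps = 1e-7) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  y <- as.numeric(y_true)
  p <- pmin(pmax(as.numeric(y_pred), eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
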