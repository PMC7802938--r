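test_that("leaky ReLU follows the two-branch definition", {
  expect_equal(leaky_relu(5, 0.01), 5)
  expect_equal(leaky_relu(-10, 0.01), -0.1)
  expect_equal(leaky_relu(0, 0.3), 0)
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(leaky_relu(x, 0.2), ifelse(x >= 0, x, 0.2 * x))
  expect_error(leaky_relu(1, -0.1), "non-negative")
})

test_that("sigmoid maps to (0,1), is symmetric, and does not overflow", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1000), 1, tolerance = 1e-12)
  expect_equal(sigmoid(-1000), 0, tolerance = 1e-12)
  expect_true(all(is.finite(sigmoid(c(-1e3, 1e3)))))
  x <- seq(-8, 8, by = 0.37)
  expect_equal(sigmoid(-x), 1 - sigmoid(x), tolerance = 1e-12)
  expect_true(all(sigmoid(x) > 0 & sigmoid(x) < 1))
})

test_that("binary cross-entropy matches the closed form and is non-negative", {
  expect_equal(binary_cross_entropy(1, 1), 0, tolerance = 1e-6)
  expect_equal(binary_cross_entropy(1, 0.5), log(2))
  expect_equal(binary_cross_entropy(0, 0.5), log(2))
  set.seed(4)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50, 0.01, 0.99)
  expect_equal(binary_cross_entropy(y, p),
               -mean(y * log(p) + (1 - y) * log(1 - p)))
  expect_gte(binary_cross_entropy(y, p), 0)
  # equality only at the (clipped) target
  expect_lt(binary_cross_entropy(y, ifelse(y == 1, 1, 0)), 1e-5)
})

test_that("the default configuration reproduces the reference layer table", {
  sh <- network_shapes(network_config())
  expect_equal(nrow(sh), 8)
  expect_equal(sh$output,
               c("128x128x32", "64x64x64", "32x32x128", "32x32x128",
                 "64x64x64", "128x128x32", "256x256x32", "256x256x1"))
  expect_equal(sh$input[1], "256x256x3")
  expect_equal(sh$filters[4], "3x3x256, 3x3x128")
})

test_that("derived bottleneck/decoder filters follow the reference pattern", {
  cfg <- network_config(input_height = 64, input_width = 64,
                        down_filters = c(8, 16, 32))
  expect_equal(cfg$bottleneck_filters, c(64L, 32L))
  expect_equal(cfg$up_filters, list(c(32L, 16L), c(16L, 8L), 8L))
})

test_that("invalid input sizes are rejected", {
  expect_error(network_config(input_height = 100, input_width = 100),
               "divisible")
  cfg <- network_config(input_height = 16, input_width = 16,
                        down_filters = c(2, 2))
  net <- build_network(cfg)
  expect_error(segment_tile(net, array(0.5, c(8, 8, 3))),
               "expected 16x16x3.*8x8x3")
})

test_that("forward pass emits probabilities strictly inside (0,1) with the input shape", {
  cfg <- network_config(input_height = 32, input_width = 32,
                        down_filters = c(4, 8, 8))
  net <- build_network(cfg, seed = 3)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- segment_tile(net, x)
  expect_equal(dim(p), c(32, 32))
  expect_gt(min(p), 0)
  expect_lt(max(p), 1)
  # per-module tensor shapes agree with the analytic audit
  sh <- network_shapes(cfg)
  expect_equal(sh$output[nrow(sh)], "32x32x1")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- network_config(input_height = 8, input_width = 8,
                        down_filters = c(2, 3), dropout_rate = 0)
  net <- build_network(cfg, seed = 2)
  set.seed(9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  fw <- plantunet:::net_forward(net, x, train = TRUE)
  lg <- plantunet:::bce_with_logits(fw$logits, y)
  grads <- plantunet:::net_backward(net, fw$cache, lg$grad)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      for (ii in sample(length(g), min(3, length(g)))) {
        np <- net
        np$params[[nm]][[slot]][ii] <- np$params[[nm]][[slot]][ii] + eps
        lp <- plantunet:::bce_with_logits(
          plantunet:::net_forward(np, x)$logits, y)$loss
        nn <- net
        nn$params[[nm]][[slot]][ii] <- nn$params[[nm]][[slot]][ii] - eps
        lm <- plantunet:::bce_with_logits(
          plantunet:::net_forward(nn, x)$logits, y)$loss
        fd <- (lp - lm) / (2 * eps)
        expect_equal(g[ii], fd, tolerance = 1e-3,
                     label = sprintf("grad %s$%s[%d]", nm, slot, ii))
      }
    }
  }
})

test_that("one small optimizer step strictly decreases the loss of a pair", {
  cfg <- network_config(input_height = 8, input_width = 8,
                        down_filters = c(2, 3), dropout_rate = 0)
  net <- build_network(cfg, seed = 5)
  set.seed(11)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- plantunet:::net_forward(net, x, train = TRUE)
  lg <- plantunet:::bce_with_logits(fw$logits, y)
  grads <- plantunet:::net_backward(net, fw$cache, lg$grad)
  st <- plantunet:::adam_init(net$params)
  upd <- plantunet:::adam_step(net$params, grads, st, 1e-3)
  net$params <- upd$params
  l2 <- plantunet:::bce_with_logits(
    plantunet:::net_forward(net, x)$logits, y)$loss
  expect_lt(l2, lg$loss)
})

test_that("checkpoints round-trip parameters and configuration", {
  cfg <- network_config(input_height = 16, input_width = 16,
                        down_filters = c(2, 2))
  net <- build_network(cfg, seed = 7)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f)
  net2 <- load_checkpoint(f)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(segment_tile(net, x), segment_tile(net2, x))
  expect_equal(net2$config$down_filters, cfg$down_filters)
})
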