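test_that("dataset expansion yields exactly 4 variants per pair", {
  pairs <- lapply(1:3, function(i) toy_pair(seed = i, id = paste0("p", i)))
  out <- expand_dataset(pairs, seed = 1)
  expect_length(out, 12)
  for (p in out) {
    expect_s3_class(p, "annotated_pair")
    expect_true(all(p$mask %in% c(0L, 1L)))
    expect_equal(dim(p$image)[1:2], dim(p$mask))
  }
  # deterministic in content given the seed
  out2 <- expand_dataset(pairs, seed = 1)
  expect_identical(lapply(out, `[[`, "mask"), lapply(out2, `[[`, "mask"))
  expect_error(expand_dataset(list()), "empty")
})

test_that("mirror and rotation preserve foreground area; translation may clip", {
  for (s in 1:5) {
    p <- toy_pair(seed = s)
    out <- expand_dataset(list(p), seed = s)
    n0 <- sum(p$mask)
    expect_identical(sum(out[[2]]$mask), n0)  # mirror
    expect_identical(sum(out[[4]]$mask), n0)  # rotation (quarter turns)
    expect_lte(sum(out[[3]]$mask), n0)        # translation clips at borders
  }
})

test_that("elastic deformation is seeded, identity at sigma 0, and binary", {
  p <- toy_pair(seed = 3)
  expect_identical(elastic_deform(p, sigma = 0), p)
  d1 <- elastic_deform(p, grid = 3, sigma = 6, seed = 42)
  d2 <- elastic_deform(p, grid = 3, sigma = 6, seed = 42)
  expect_identical(d1$image, d2$image)
  expect_identical(d1$mask, d2$mask)
  d3 <- elastic_deform(p, grid = 3, sigma = 6, seed = 43)
  expect_false(identical(d1$mask, d3$mask) && identical(d1$image, d3$image))
  expect_true(all(d1$mask %in% c(0L, 1L)))
})

test_that("a sigma-10 deformation preserves blob area to within 15% typically", {
  # study-scale check: 256x256 frame, compact blob, 100 seeded deformations;
  # the field is area-preserving in expectation and the typical |change| is
  # well inside 15% (individual draws can reach ~20%: the divergence of a
  # Normal(0,10) field on a 3x3 grid has heavy enough tails)
  mask <- matrix(0L, 256, 256)
  for (i in 1:256) for (j in 1:256)
    if ((i - 128)^2 / 60^2 + (j - 120)^2 / 35^2 <= 1) mask[i, j] <- 1L
  img <- array(0.5, c(256, 256, 3))
  p <- annotated_pair(img, mask, "blob")
  a0 <- sum(mask)
  rel <- vapply(1:100, function(s) {
    (sum(elastic_deform(p, 3, 10, seed = s)$mask) - a0) / a0
  }, numeric(1))
  expect_lt(mean(abs(rel)), 0.15)    # typical area change
  expect_lt(abs(mean(rel)), 0.05)    # no systematic growth or shrinkage
  expect_lt(median(abs(rel)), 0.15)
})

test_that("training reduces the loss on a separable toy problem", {
  # masks are (thresholded) green blobs; a reduced net must learn them
  set.seed(21)
  mk <- function(s) {
    sc <- generate_scene_robust(seed_base = s, shape = c(32, 32),
                                n_plants_range = c(1, 2))
    annotated_pair(sc$image, sc$mask, paste0("s", s))
  }
  train_set <- lapply(1:6, mk)
  val_set <- lapply(7:8, mk)
  cfg <- network_config(input_height = 32, input_width = 32,
                        down_filters = c(4, 8, 8))
  net <- build_network(cfg, seed = 1)
  tc <- training_config(steps_per_epoch = 30, max_epochs = 10,
                        patience_epochs = 10, elastic_sigma = 1.25, seed = 1)
  res <- train(net, train_set, val_set, tc)
  h <- res$history
  expect_equal(nrow(h), 10)
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
  # the returned parameters realize the best observed validation loss
  vl <- mean(vapply(val_set, function(v) {
    plantunet:::bce_with_logits(
      plantunet:::net_forward(res$network, v$image)$logits, v$mask)$loss
  }, numeric(1)))
  expect_equal(vl, min(h$val_loss), tolerance = 1e-10)
})

test_that("training on all-background masks drives the output toward zero", {
  img <- array(runif(32 * 32 * 3, 0, 0.6), c(32, 32, 3))
  p <- annotated_pair(img, matrix(0L, 32, 32), "bg")
  cfg <- network_config(input_height = 32, input_width = 32,
                        down_filters = c(2, 4), dropout_rate = 0)
  net <- build_network(cfg, seed = 2)
  tc <- training_config(learning_rate = 1e-3, steps_per_epoch = 40,
                        max_epochs = 5, patience_epochs = 5,
                        elastic_sigma = 0, seed = 3)
  res <- train(net, list(p), list(p), tc)
  expect_lt(tail(res$history$train_loss, 1), 0.05)
  expect_lt(mean(segment_tile(res$network, img)), 0.1)
})

test_that("a fixed seed reproduces the loss history", {
  p <- toy_pair(H = 16, W = 16, seed = 5)
  cfg <- network_config(input_height = 16, input_width = 16,
                        down_filters = c(2, 2))
  tc <- training_config(steps_per_epoch = 5, max_epochs = 3,
                        patience_epochs = 3, elastic_sigma = 2, seed = 99)
  r1 <- train(build_network(cfg, seed = 1), list(p), list(p), tc)
  r2 <- train(build_network(cfg, seed = 1), list(p), list(p), tc)
  expect_identical(r1$history, r2$history)
})
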