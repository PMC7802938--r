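# Independent brute-force oracles used to pin down the geometry and metric
# implementations, plus small fixture builders. Everything here is written
# naively on purpose: exhaustive loops, no shortcuts shared with the package.

# connected random blob: union of a chain of overlapping discs
random_blob <- function(H = 30, W = 30, n_discs = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(0L, H, W)
  ctr <- c(runif(1, H * 0.3, H * 0.7), runif(1, W * 0.3, W * 0.7))
  for (d in seq_len(n_discs)) {
    r <- runif(1, 2, 5)
    for (i in 1:H) for (j in 1:W)
      if ((i - ctr[1])^2 + (j - ctr[2])^2 <= r^2) m[i, j] <- 1L
    step <- runif(2, -r, r)
    ctr <- pmin(pmax(ctr + step, c(3, 3)), c(H - 2, W - 2))
  }
  m
}

# exhaustive max pairwise distance over an m x 2 coordinate set
brute_diameter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(pts) - 1))
    for (j in (i + 1):nrow(pts)) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d > best) best <- d
    }
  best
}

# minimal enclosing circle radius by exhaustive candidate circles over the
# convex hull (MEC is determined by 2 or 3 hull points)
brute_mec_radius <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1) return(0)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  p <- pts[h, , drop = FALSE]
  n <- nrow(p)
  contains_all <- function(ctr, r2) {
    all((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <= r2 + 1e-9)
  }
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ctr <- (p[i, ] + p[j, ]) / 2
    r2 <- sum((p[i, ] - ctr)^2)
    if (contains_all(ctr, r2)) best <- min(best, sqrt(r2))
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- p[i, ]; b <- p[j, ]; c <- p[k, ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                  c[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
               sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
               sum(c^2) * (b[1] - a[1])) / d
      ctr <- c(ux, uy)
      r2 <- sum((a - ctr)^2)
      if (contains_all(ctr, r2)) best <- min(best, sqrt(r2))
    }
  }
  best
}

# four-way pixel tally by explicit double loop
brute_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
      else tn <- tn + 1L
    }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small annotated pair with a random rectangle foreground
toy_pair <- function(H = 16, W = 16, seed = 1, id = "toy") {
  set.seed(seed)
  mask <- matrix(0L, H, W)
  r0 <- sample(2:(H - 6), 1); c0 <- sample(2:(W - 6), 1)
  mask[r0:(r0 + 4), c0:(c0 + 4)] <- 1L
  img <- array(runif(H * W * 3, 0, 0.3), c(H, W, 3))
  img[, , 2][mask == 1] <- 0.8  # green foreground
  annotated_pair(img, mask, id)
}

# single-instance helper: wrap a pixel matrix as the only plant of a mask
instance_from_mask <- function(mask, min_area = 1) {
  inst <- label_plants(mask, min_area = min_area)
  stopifnot(length(inst) == 1)
  inst[[1]]
}
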