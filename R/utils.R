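# internal helpers shared across modules

# run expr with a temporarily seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# derive a per-step substream seed below 2^31 from a base seed
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

# concatenate two H x W x C arrays along the channel axis
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# ensure an image array is H x W x 3 (replicate grayscale, drop alpha)
as_rgb_array <- function(x, what = "image") {
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  d <- dim(x)
  if (length(d) != 3L) stop(what, " must be an H x W x C array")
  if (d[3] == 1L) x <- array(rep(x, 3L), c(d[1], d[2], 3L))
  else if (d[3] == 4L) {
    warning(what, ": dropping alpha channel")
    x <- x[, , 1:3, drop = FALSE]
  } else if (d[3] != 3L) stop(what, " has unsupported channel count ", d[3])
  x
}

# reflection-pad (no edge repeat) an H x W x C array or matrix on the
# bottom/right; pad must be < the corresponding dimension
pad_reflect <- function(x, bottom, right) {
  m <- is.matrix(x)
  if (m) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (bottom > d[1] - 1 || right > d[2] - 1)
    stop("reflection pad larger than image")
  ri <- c(seq_len(d[1]), if (bottom > 0) d[1] - seq_len(bottom))
  ci <- c(seq_len(d[2]), if (right > 0) d[2] - seq_len(right))
  out <- x[ri, ci, , drop = FALSE]
  if (m) out[, , 1] else out
}

# smooth (cubic-spline) upsampling of a small g x g node grid to H x W;
# nodes are placed at evenly spaced positions spanning the full image
upsample_grid <- function(nodes, H, W) {
  g <- nrow(nodes)
  rp <- seq(1, H, length.out = g)
  cp <- seq(1, W, length.out = g)
  # rows of nodes -> full width
  wide <- t(vapply(seq_len(g), function(i) {
    if (g == 1) rep(nodes[i, 1], W)
    else spline(cp, nodes[i, ], xout = seq_len(W))$y
  }, numeric(W)))
  # columns -> full height
  vapply(seq_len(W), function(j) {
    if (g == 1) rep(wide[1, j], H)
    else spline(rp, wide[, j], xout = seq_len(H))$y
  }, numeric(H))
}

# max pairwise distance of an m x 2 point set, via convex hull (exact)
set_diameter <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 2) return(0)
  h <- chull(pts[, 2], pts[, 1])
  if (length(h) < 2) return(0)
  max(dist(pts[h, , drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
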