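#' Specification of one synthetic seedling plant
#'
#' A rosette of elliptical leaves around a centre, with leaf orientations
#' drawn about a dominant azimuth plane: the top-view geometry of a young
#' maize plant whose expanded leaves lie along a vertical plane. Ellipse
#' leaves keep the analytic ground truth exact while preserving the
#' difficulty of the traits.
#'
#' @param center (row, col) centre in pixels.
#' @param azimuth_deg true azimuth-plane angle beta* in \[0, 180).
#' @param n_leaves number of leaves (2-8).
#' @param leaf_length full leaf length in pixels.
#' @param leaf_width full leaf width in pixels (< leaf_length).
#' @param azimuth_concentration how tightly leaves align to the azimuth
#'   plane; the angular jitter of a leaf is Normal with sd
#'   `45 / azimuth_concentration` degrees (default 5, i.e. 9 degrees).
#' @param color base leaf RGB in \[0, 1\]; each leaf gets a small jitter.
#' @return object of class `synthetic_plant_spec`.
#' @export
synthetic_plant_spec <- function(center, azimuth_deg, n_leaves = 4,
                                 leaf_length = 40, leaf_width = 8,
                                 azimuth_concentration = 5,
                                 color = c(0.20, 0.52, 0.16)) {
  stopifnot(leaf_length > leaf_width, leaf_width > 0,
            n_leaves >= 2, n_leaves <= 8, azimuth_concentration > 0)
  structure(list(center = center, azimuth_deg = azimuth_deg %% 180,
                 n_leaves = as.integer(n_leaves),
                 leaf_length = leaf_length, leaf_width = leaf_width,
                 azimuth_concentration = azimuth_concentration,
                 color = color),
            class = "synthetic_plant_spec")
}

# pixel set (1-based m x 2) of a rotated ellipse, centre (r, c), semi-axes
# a (along direction phi, degrees) and b
ellipse_pixels <- function(H, W, center, a, b, phi_deg) {
  phi <- phi_deg * pi / 180
  ext <- ceiling(max(a, b)) + 1
  ri <- max(1, floor(center[1] - ext)):min(H, ceiling(center[1] + ext))
  ci <- max(1, floor(center[2] - ext)):min(W, ceiling(center[2] + ext))
  gr <- rep(ri, times = length(ci)) - center[1]
  gc <- rep(ci, each = length(ri)) - center[2]
  # direction convention: angle beta has unit vector (sin beta, cos beta)
  # in (row, col) coordinates, so beta = 0 points along the image x-axis
  u <- gr * sin(phi) + gc * cos(phi)
  v <- -gr * cos(phi) + gc * sin(phi)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(ri, times = length(ci))[keep],
        col = rep(ci, each = length(ri))[keep])
}

# render one plant: leaf ellipses on alternating sides of the azimuth
# plane; returns pixel set, per-pixel colours, and the realized leaf count.
# Leaves are offset so every ellipse covers the plant centre, keeping the
# plant a single 8-connected component (verified by the caller).
render_plant <- function(spec, H, W) {
  sd_deg <- 45 / spec$azimuth_concentration
  pix <- NULL
  col <- NULL
  for (i in seq_len(spec$n_leaves)) {
    side <- if (i %% 2 == 0) 180 else 0
    phi <- spec$azimuth_deg + side + rnorm(1, 0, sd_deg)
    len <- spec$leaf_length * runif(1, 0.75, 1.0)
    wid <- max(2.2, spec$leaf_width * runif(1, 0.8, 1.1))
    a <- len / 2
    b <- wid / 2
    ctr <- spec$center + 0.55 * a * c(sin(phi * pi / 180),
                                      cos(phi * pi / 180))
    p <- ellipse_pixels(H, W, ctr, a, b, phi)
    if (nrow(p) == 0) next
    leaf_col <- pmin(pmax(spec$color + rnorm(3, 0, 0.03), 0), 1)
    pix <- rbind(pix, p)
    col <- rbind(col, matrix(leaf_col, nrow(p), 3, byrow = TRUE))
  }
  if (is.null(pix)) stop("plant rendered no pixels (off-frame spec?)")
  dup <- duplicated(pix)
  list(pixels = pix[!dup, , drop = FALSE], colors = col[!dup, , drop = FALSE])
}

# soil background: low-frequency brown noise plus fine grain
render_soil <- function(H, W) {
  base <- c(0.42, 0.31, 0.19)
  g <- 6
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    nodes <- matrix(base[ch] + runif(g * g, -0.05, 0.05), g, g)
    img[, , ch] <- upsample_grid(nodes, H, W) +
      matrix(rnorm(H * W, 0, 0.02), H, W)
  }
  pmin(pmax(img, 0), 1)
}

#' Render a ground-truthed synthetic seedling scene
#'
#' Draws the plants of `specs` as green leaf rosettes on a brown
#' soil-textured background with the optional distractors of real field
#' scenes -- a dark drip-tape stripe and small green weed blobs -- under a
#' random global brightness factor. Returns the image, the exact binary
#' mask (the union of the rendered leaf regions; weeds are non-plant and
#' excluded), and the analytic per-plant ground truth: exact pixel
#' coverage, exact contour-based circumscribed radius, exact bounding-box
#' extents, the generating azimuth beta*, and the realized colour means.
#'
#' @param specs list of [synthetic_plant_spec()]; plants must not overlap.
#' @param shape (H, W) of the scene (default 256 x 256).
#' @param seed RNG seed; the same seed reproduces the scene exactly.
#' @param drip_tape_prob probability of a drip-tape stripe (default 0.5).
#' @param n_weeds_range range of the number of small weed blobs
#'   (default 0 to 3); weed blobs stay below ~15 px so the default
#'   phenotyping area filter rejects them.
#' @param brightness_range global brightness factor range
#'   (default 0.7-1.3).
#' @param merge_allowed if FALSE (default), overlapping plants are an
#'   error.
#' @return object of class `synthetic_scene`: `image` (H x W x 3), `mask`
#'   (H x W in \{0, 1\}), `truth` (data.frame, one row per plant with a
#'   `true_azimuth_deg` column), `specs`, `seed`.
#' @export
render_scene <- function(specs, shape = c(256, 256), seed = 1,
                         drip_tape_prob = 0.5, n_weeds_range = c(0, 3),
                         brightness_range = c(0.7, 1.3),
                         merge_allowed = FALSE) {
  H <- shape[1]; W <- shape[2]
  with_local_seed(seed, {
    img <- render_soil(H, W)
    # drip-tape stripe
    if (runif(1) < drip_tape_prob) {
      wd <- sample(3:6, 1)
      shade <- runif(1, 0.12, 0.18)
      if (runif(1) < 0.5) {
        c0 <- sample(seq_len(max(1, W - wd)), 1)
        img[, c0:(c0 + wd - 1), ] <- shade
      } else {
        r0 <- sample(seq_len(max(1, H - wd)), 1)
        img[r0:(r0 + wd - 1), , ] <- shade
      }
    }
    # plants: render each as a single connected component
    mask <- matrix(0L, H, W)
    plant_pix <- vector("list", length(specs))
    plant_col <- vector("list", length(specs))
    for (k in seq_along(specs)) {
      stopifnot(inherits(specs[[k]], "synthetic_plant_spec"))
      for (try in 1:8) {
        rp <- render_plant(specs[[k]], H, W)
        sub <- matrix(0L, H, W)
        sub[rp$pixels] <- 1L
        if (max(cpp_label8(sub)) == 1L) break
        if (try == 8) stop("could not render plant ", k,
                           " as a single connected component")
      }
      flat <- rp$pixels[, 1] + (rp$pixels[, 2] - 1L) * H
      if (!merge_allowed && any(mask[flat] == 1L))
        stop("plants ", k, " overlaps an earlier plant; ",
             "set merge_allowed = TRUE to permit merged rosettes")
      mask[flat] <- 1L
      plant_pix[[k]] <- rp$pixels
      plant_col[[k]] <- rp$colors
    }
    # weed distractors: small green blobs on bare soil, not in the mask
    n_weeds <- sample(seq(n_weeds_range[1], n_weeds_range[2]), 1)
    for (w in seq_len(n_weeds)) {
      for (try in 1:20) {
        ctr <- c(runif(1, 3, H - 2), runif(1, 3, W - 2))
        p <- ellipse_pixels(H, W, ctr, runif(1, 1.2, 2.5),
                            runif(1, 0.8, 1.5), runif(1, 0, 180))
        if (nrow(p) == 0) next
        flat <- p[, 1] + (p[, 2] - 1L) * H
        if (all(mask[flat] == 0L)) {
          wc <- pmin(pmax(c(0.18, 0.38, 0.14) + rnorm(3, 0, 0.03), 0), 1)
          for (ch in 1:3) img[flat + (ch - 1) * H * W] <- wc[ch]
          break
        }
      }
    }
    # paint plants over background/distractors
    for (k in seq_along(specs)) {
      flat <- plant_pix[[k]][, 1] + (plant_pix[[k]][, 2] - 1L) * H
      for (ch in 1:3)
        img[flat + (ch - 1) * H * W] <- plant_col[[k]][, ch]
    }
    bright <- runif(1, brightness_range[1], brightness_range[2])
    img <- pmin(pmax(img * bright, 0), 1)
    truth <- do.call(rbind, lapply(seq_along(specs), function(k) {
      px <- plant_pix[[k]]
      px0 <- cbind(row = px[, 1] - 1, col = px[, 2] - 1)
      flat <- px[, 1] + (px[, 2] - 1L) * H
      r <- img[flat]; g <- img[flat + H * W]; b <- img[flat + 2 * H * W]
      hsv <- rgb2hsv(rbind(r, g, b), maxColorValue = 1)
      a <- hsv["h", ] * 2 * pi
      data.frame(
        id = k,
        row = mean(px0[, 1]), col = mean(px0[, 2]),
        coverage_px = nrow(px0),
        radius_px = set_diameter(px0) / 2,
        aspect_ratio = (diff(range(px0[, 2])) + 1) /
          (diff(range(px0[, 1])) + 1),
        true_azimuth_deg = specs[[k]]$azimuth_deg,
        r_mean = mean(r), g_mean = mean(g), b_mean = mean(b),
        h_mean = (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360,
        s_mean = mean(hsv["s", ]), v_mean = mean(hsv["v", ]))
    }))
    structure(list(image = img, mask = mask, truth = truth, specs = specs,
                   seed = seed),
              class = "synthetic_scene")
  })
}

#' Random plant layout for a scene
#'
#' Places plants on a jittered planting grid (the row-and-spacing layout of
#' a real plot) with leaf sizes scaled to the grid cell so neighbouring
#' rosettes do not collide. Each scene is drawn at one of two growth
#' stages, emulating the two imaging time points of seedling trials: V3
#' (three expanded leaves, smaller rosettes) or V6 (six, near full cell
#' size). The stage scales every leaf in the scene, so plant sizes -- and
#' with them coverage and radius -- span a realistic range across a corpus.
#'
#' @param n_plants number of plants.
#' @param shape scene (H, W).
#' @param azimuth_deg common true azimuth for all plants, or NULL (each
#'   plant draws its own uniformly from \[0, 180)).
#' @param azimuth_concentration leaf alignment tightness (see
#'   [synthetic_plant_spec()]).
#' @param n_leaves_range range of leaves per plant (default 3-6).
#' @param stage_scales length-2 list of size-factor ranges for the V3 and
#'   V6 stages (defaults `c(0.7, 0.8)` and `c(0.95, 1.1)`); one stage is
#'   drawn per scene with equal probability.
#' @param seed optional RNG seed.
#' @return list of [synthetic_plant_spec()].
#' @export
random_plant_specs <- function(n_plants, shape = c(256, 256),
                               azimuth_deg = NULL,
                               azimuth_concentration = 5,
                               n_leaves_range = c(3, 6),
                               stage_scales = list(v3 = c(0.7, 0.8),
                                                   v6 = c(0.95, 1.1)),
                               seed = NULL) {
  H <- shape[1]; W <- shape[2]
  with_local_seed(seed, {
    gr <- max(1, floor(sqrt(n_plants * H / W)))
    gc <- ceiling(n_plants / gr)
    cell_h <- H / gr; cell_w <- W / gc
    cell_min <- min(cell_h, cell_w)
    cells <- sample(gr * gc, n_plants)
    stage <- stage_scales[[sample(length(stage_scales), 1)]]
    scene_scale <- runif(1, stage[1], stage[2])
    lapply(seq_len(n_plants), function(k) {
      i <- (cells[k] - 1) %% gr
      j <- (cells[k] - 1) %/% gr
      ctr <- c(cell_h * (i + 0.5) + runif(1, -0.1, 0.1) * cell_h,
               cell_w * (j + 0.5) + runif(1, -0.1, 0.1) * cell_w)
      len <- cell_min * runif(1, 0.45, 0.58) * scene_scale
      synthetic_plant_spec(
        center = ctr,
        azimuth_deg = azimuth_deg %||% runif(1, 0, 180),
        n_leaves = sample(seq(n_leaves_range[1], n_leaves_range[2]), 1),
        leaf_length = len,
        leaf_width = max(2.4, len * runif(1, 0.18, 0.28)),
        azimuth_concentration = azimuth_concentration)
    })
  })
}

#' Generate a ground-truthed synthetic corpus on disk
#'
#' Writes train/val/test splits in the dataset directory convention of the
#' training module -- `<split>/images/*.png` and `<split>/masks/*.png` with
#' matching stems, masks as \{0, 255\} PNG -- plus a `truth.csv` per split
#' holding the analytic per-plant ground truth. Splits use disjoint seed
#' substreams; the identical call reproduces the identical corpus.
#'
#' @param out_dir output directory (created if missing).
#' @param n_train,n_val,n_test scenes per split.
#' @param shape scene size (default 256 x 256).
#' @param n_plants_range plants per scene (default 4 to 6).
#' @param seed master seed (default 7).
#' @param ... further arguments passed to [render_scene()] and
#'   [random_plant_specs()] (`azimuth_concentration`, `drip_tape_prob`,
#'   `n_weeds_range`, `brightness_range`).
#' @return invisibly, a manifest data.frame (split, scene, path).
#' @export
generate_corpus <- function(out_dir, n_train, n_val, n_test,
                            shape = c(256, 256), n_plants_range = c(4, 6),
                            seed = 7, azimuth_concentration = 5,
                            drip_tape_prob = 0.5, n_weeds_range = c(0, 3),
                            brightness_range = c(0.7, 1.3)) {
  splits <- list(train = n_train, val = n_val, test = n_test)
  manifest <- list()
  for (si in seq_along(splits)) {
    split <- names(splits)[si]
    n <- splits[[split]]
    dir.create(file.path(out_dir, split, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, split, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    truth_rows <- list()
    for (i in seq_len(n)) {
      sc <- generate_scene_robust(
        seed_base = derive_seed(seed, si * 100000 + i),
        shape = shape, n_plants_range = n_plants_range,
        azimuth_concentration = azimuth_concentration,
        drip_tape_prob = drip_tape_prob, n_weeds_range = n_weeds_range,
        brightness_range = brightness_range)
      stem <- sprintf("scene_%03d", i)
      write_image(sc$image, file.path(out_dir, split, "images",
                                      paste0(stem, ".png")))
      write_mask(sc$mask, file.path(out_dir, split, "masks",
                                    paste0(stem, ".png")))
      tr <- sc$truth
      tr$scene <- stem
      truth_rows[[i]] <- tr
      manifest[[length(manifest) + 1]] <-
        data.frame(split = split, scene = stem,
                   path = file.path(out_dir, split, "images",
                                    paste0(stem, ".png")))
    }
    truth <- do.call(rbind, truth_rows)
    write.csv(truth[, c("scene", setdiff(names(truth), "scene"))],
              file.path(out_dir, split, "truth.csv"), row.names = FALSE)
  }
  invisible(do.call(rbind, manifest))
}

#' Generate one scene in memory (with layout retry on plant collision)
#'
#' Convenience wrapper: draws a random layout and renders it; on the rare
#' collision of two rosettes the layout is redrawn from the next substream
#' seed.
#'
#' @param seed_base seed of the first attempt.
#' @inheritParams generate_corpus
#' @param azimuth_deg optional common azimuth (see [random_plant_specs()]).
#' @return a `synthetic_scene`.
#' @export
generate_scene_robust <- function(seed_base, shape = c(256, 256),
                                  n_plants_range = c(4, 6),
                                  azimuth_deg = NULL,
                                  azimuth_concentration = 5,
                                  drip_tape_prob = 0.5,
                                  n_weeds_range = c(0, 3),
                                  brightness_range = c(0.7, 1.3)) {
  for (try in 0:19) {
    sd <- derive_seed(seed_base, try)
    n_plants <- with_local_seed(sd, sample(
      seq(n_plants_range[1], n_plants_range[2]), 1))
    specs <- random_plant_specs(n_plants, shape, azimuth_deg = azimuth_deg,
                                azimuth_concentration = azimuth_concentration,
                                seed = sd + 1L)
    sc <- tryCatch(render_scene(specs, shape, seed = sd + 2L,
                                drip_tape_prob = drip_tape_prob,
                                n_weeds_range = n_weeds_range,
                                brightness_range = brightness_range),
                   error = function(e) NULL)
    if (!is.null(sc)) return(sc)
  }
  stop("could not generate a collision-free scene in 20 attempts")
}
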