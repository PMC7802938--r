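#' Physical pixel calibration
#'
#' Scale reference derived from size-known markers placed in the scene:
#' physical length of one pixel edge.
#'
#' @param cm_per_pixel centimetres per pixel edge; strictly positive.
#' @return object of class `calibration`.
#' @export
calibration <- function(cm_per_pixel) {
  if (!is.numeric(cm_per_pixel) || cm_per_pixel <= 0)
    stop("cm_per_pixel must be strictly positive")
  structure(list(cm_per_pixel = cm_per_pixel), class = "calibration")
}

#' Label individual plants in a binary mask
#'
#' Finds 8-connected foreground components with area >= `min_area`, traces
#' the outer contour of each (Moore-neighbour tracing), and returns one
#' plant instance per component, ordered left-to-right by centroid column.
#' Pixel coordinates are 0-based (row, col), origin at the top-left.
#'
#' @param mask H x W matrix in \{0, 1\}.
#' @param min_area minimum component area in pixels (default 50); smaller
#'   blobs (weeds, noise) are discarded.
#' @return list of `plant_instance` objects with fields `pixels` (m x 2
#'   matrix), `contour` (ordered boundary coordinates), `centroid`
#'   (row, col), `label`.
#' @export
label_plants <- function(mask, min_area = 50) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  lab <- cpp_label8(mask)
  n <- max(lab)
  if (n == 0) return(list())
  inst <- list()
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    pixels <- cbind(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
    contour <- cpp_trace_contour(lab, l)
    colnames(contour) <- c("row", "col")
    inst[[length(inst) + 1]] <- structure(
      list(pixels = pixels, contour = contour,
           centroid = c(row = mean(pixels[, 1]), col = mean(pixels[, 2])),
           label = l),
      class = "plant_instance")
  }
  inst[order(vapply(inst, function(i) i$centroid[["col"]], numeric(1)))]
}

#' Circumscribed radius of a plant
#'
#' Half the maximum Euclidean distance between any two pixels on the
#' plant's outline (the half-diameter of the contour). Computed exactly via
#' the convex hull of the boundary pixels, on which the farthest pair must
#' lie. A single-pixel instance has radius 0.
#'
#' @param instance a `plant_instance`.
#' @param cal optional [calibration()]; when given, the radius is also
#'   returned in cm.
#' @return named vector with `radius_px` and, with calibration,
#'   `radius_cm`.
#' @export
circumscribed_radius <- function(instance, cal = NULL) {
  stopifnot(inherits(instance, "plant_instance"))
  r <- set_diameter(instance$contour) / 2
  if (is.null(cal)) c(radius_px = r)
  else c(radius_px = r, radius_cm = r * cal$cm_per_pixel)
}

#' Bounding-box aspect ratio
#'
#' Ratio of the x-direction (column) extent to the y-direction (row)
#' extent of the axis-aligned bounding box, each extent counted as
#' `max - min + 1` pixels. A single pixel has ratio 1.
#'
#' @param instance a `plant_instance`.
#' @return positive scalar.
#' @export
aspect_ratio <- function(instance) {
  stopifnot(inherits(instance, "plant_instance"))
  px <- instance$pixels
  L <- diff(range(px[, 2])) + 1
  H <- diff(range(px[, 1])) + 1
  L / H
}

#' Plant coverage
#'
#' Number of pixels occupied by the plant, and -- when a calibration is
#' supplied -- the corresponding ground area in cm^2
#' (`pixels * cm_per_pixel^2`).
#'
#' @param instance a `plant_instance`.
#' @param cal optional [calibration()].
#' @return named vector with `coverage_px` and, with calibration,
#'   `coverage_cm2`.
#' @export
coverage <- function(instance, cal = NULL) {
  stopifnot(inherits(instance, "plant_instance"))
  C <- nrow(instance$pixels)
  if (is.null(cal)) c(coverage_px = C)
  else c(coverage_px = C, coverage_cm2 = C * cal$cm_per_pixel^2)
}

#' Azimuth-plane angle of a plant
#'
#' The expanded leaves of a young maize plant lie along a vertical plane
#' whose top-view trace is a line. That line is fitted as the principal
#' axis (leading eigenvector of the 2x2 covariance) of the plant's pixel
#' coordinates, and beta is its angle to the north-south reference axis,
#' folded to \[0, 180). By default the reference is the image x-axis
#' (acquisition convention: image left = north); use `north_axis = "y"`
#' for scenes where north is up.
#'
#' An instance whose coordinate covariance is nearly isotropic
#' (eigenvalue ratio < 1.2) has no well-defined azimuth; the angle is still
#' returned but flagged.
#'
#' @param instance a `plant_instance` with at least 2 pixels.
#' @param north_axis `"x"` (default) or `"y"`.
#' @return list with `beta_deg` in \[0, 180), `ok` (FALSE when
#'   ill-conditioned), and `anisotropy` (eigenvalue ratio).
#' @export
azimuth_angle <- function(instance, north_axis = c("x", "y")) {
  stopifnot(inherits(instance, "plant_instance"))
  north_axis <- match.arg(north_axis)
  px <- instance$pixels
  if (nrow(px) < 2) stop("azimuth requires at least 2 pixels")
  S <- stats::cov(px)
  e <- eigen(S, symmetric = TRUE)
  v <- e$vectors[, 1]
  theta <- (atan2(v[1], v[2]) * 180 / pi) %% 180
  if (north_axis == "y") theta <- (90 - theta) %% 180
  lam <- e$values
  ratio <- if (lam[2] <= .Machine$double.eps) Inf else lam[1] / lam[2]
  list(beta_deg = theta, ok = ratio >= 1.2, anisotropy = ratio)
}

#' Mean RGB and HSV colour of a plant region
#'
#' Means of the R, G, B channels over the instance pixels of the original
#' image, and the per-pixel HSV conversion averaged per channel. Hue (in
#' degrees, \[0, 360)) is averaged circularly to avoid the 0/360 wrap
#' artifact; saturation and value are plain means in \[0, 1\].
#'
#' @param image H x W x 3 array in \[0, 1\], same size as the mask the
#'   instance came from.
#' @param instance a `plant_instance`.
#' @param circular_hue use the circular (vector) mean for hue
#'   (default TRUE); FALSE gives the plain arithmetic mean.
#' @return list with `rgb_mean` (r, g, b) and `hsv_mean` (h, s, v).
#' @export
color_features <- function(image, instance, circular_hue = TRUE) {
  stopifnot(inherits(instance, "plant_instance"))
  image <- as_rgb_array(image)
  px <- instance$pixels
  ir <- px[, 1] + 1L
  ic <- px[, 2] + 1L
  H <- dim(image)[1]
  flat <- ir + (ic - 1L) * H
  r <- image[, , 1][flat]
  g <- image[, , 2][flat]
  b <- image[, , 3][flat]
  hsv <- rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  hdeg <- hsv["h", ] * 360
  hmean <- if (circular_hue) {
    a <- hdeg * pi / 180
    (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
  } else mean(hdeg)
  list(rgb_mean = c(r = mean(r), g = mean(g), b = mean(b)),
       hsv_mean = c(h = hmean, s = mean(hsv["s", ]), v = mean(hsv["v", ])))
}

#' Extract the full trait table of an image
#'
#' Labels the plants of a segmented mask and computes every morphological
#' and colour trait per plant: coverage (px and cm^2), circumscribed
#' radius, bounding-box aspect ratio, azimuth-plane angle, and RGB/HSV
#' colour means. Per-instance failures (e.g. an undefined azimuth) are
#' recorded in the row rather than aborting the batch.
#'
#' @param image H x W x 3 original image in \[0, 1\].
#' @param mask H x W binary segmentation of the same size.
#' @param cal optional [calibration()] (cm columns are NA without it).
#' @param min_area minimum plant area in pixels (default 50).
#' @param north_axis reference axis for the azimuth (see
#'   [azimuth_angle()]).
#' @return data.frame with one row per plant: id, row, col, coverage_px,
#'   coverage_cm2, radius_px, radius_cm, aspect_ratio, azimuth_deg,
#'   azimuth_ok, r_mean, g_mean, b_mean, h_mean, s_mean, v_mean.
#' @export
phenotype_image <- function(image, mask, cal = NULL, min_area = 50,
                           north_axis = "x") {
  image <- as_rgb_array(image)
  if (!all(dim(image)[1:2] == dim(mask)))
    stop("image and mask dimensions differ")
  empty <- data.frame(id = integer(), row = numeric(), col = numeric(),
                      coverage_px = numeric(), coverage_cm2 = numeric(),
                      radius_px = numeric(), radius_cm = numeric(),
                      aspect_ratio = numeric(), azimuth_deg = numeric(),
                      azimuth_ok = logical(), r_mean = numeric(),
                      g_mean = numeric(), b_mean = numeric(),
                      h_mean = numeric(), s_mean = numeric(),
                      v_mean = numeric())
  inst <- label_plants(mask, min_area)
  if (length(inst) == 0) return(empty)
  rows <- lapply(seq_along(inst), function(i) {
    x <- inst[[i]]
    cv <- coverage(x, cal)
    rd <- circumscribed_radius(x, cal)
    az <- tryCatch(azimuth_angle(x, north_axis),
                   error = function(e) list(beta_deg = NA_real_, ok = FALSE))
    cl <- color_features(image, x)
    data.frame(id = i, row = x$centroid[["row"]], col = x$centroid[["col"]],
               coverage_px = cv[["coverage_px"]],
               coverage_cm2 = if (is.null(cal)) NA_real_ else cv[["coverage_cm2"]],
               radius_px = rd[["radius_px"]],
               radius_cm = if (is.null(cal)) NA_real_ else rd[["radius_cm"]],
               aspect_ratio = aspect_ratio(x),
               azimuth_deg = az$beta_deg, azimuth_ok = az$ok,
               r_mean = cl$rgb_mean[["r"]], g_mean = cl$rgb_mean[["g"]],
               b_mean = cl$rgb_mean[["b"]], h_mean = cl$hsv_mean[["h"]],
               s_mean = cl$hsv_mean[["s"]], v_mean = cl$hsv_mean[["v"]])
  })
  do.call(rbind, rows)
}
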