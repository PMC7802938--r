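test_that("plant labeling separates blobs, filters small areas, orders by column", {
  m <- matrix(0L, 20, 20)
  m[3:7, 12:16] <- 1L    # right square, 25 px
  m[10:14, 2:6] <- 1L    # left square, 25 px
  inst <- label_plants(m, min_area = 1)
  expect_length(inst, 2)
  expect_equal(nrow(inst[[1]]$pixels), 25)
  expect_equal(nrow(inst[[2]]$pixels), 25)
  expect_lt(inst[[1]]$centroid[["col"]], inst[[2]]$centroid[["col"]])
  expect_identical(label_plants(matrix(0L, 5, 5)), list())
  # area filter: blobs of 30 / 20 / 3 px with min_area 10 -> 2 instances
  m2 <- matrix(0L, 30, 30)
  m2[1:5, 1:6] <- 1L; m2[10:13, 10:14] <- 1L; m2[25, 25:27] <- 1L
  expect_length(label_plants(m2, min_area = 10), 2)
})

test_that("labeling is 8-connected: diagonal pixels form one component", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:4, 1:4)] <- 1L
  inst <- label_plants(m, min_area = 1)
  expect_length(inst, 1)
  expect_equal(nrow(inst[[1]]$pixels), 4)
})

test_that("traced contours are the boundary of the component", {
  m <- matrix(0L, 12, 12)
  m[3:8, 4:10] <- 1L  # 6 x 7 rectangle
  inst <- instance_from_mask(m)
  perim <- unique(inst$contour)
  # expected: all rectangle pixels with row in {3,8} or col in {4,10} (0-based)
  exp_b <- NULL
  for (i in 3:8) for (j in 4:10)
    if (i %in% c(3, 8) || j %in% c(4, 10))
      exp_b <- rbind(exp_b, c(i - 1, j - 1))
  expect_setequal(paste(perim[, 1], perim[, 2]),
                  paste(exp_b[, 1], exp_b[, 2]))
})

test_that("circumscribed radius handles degenerate instances", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(circumscribed_radius(instance_from_mask(m))[["radius_px"]], 0)
  m2 <- matrix(0L, 6, 6); m2[1, 1] <- 1L; m2[4, 5] <- 1L  # (0,0) and (3,4)
  # two isolated pixels are two components; join via an L-shaped bridge
  m3 <- matrix(0L, 6, 6); m3[1, 1:5] <- 1L; m3[2:4, 5] <- 1L
  expect_length(label_plants(m2, min_area = 1), 2)
  i3 <- label_plants(m3, min_area = 1)[[1]]
  expect_equal(circumscribed_radius(i3)[["radius_px"]], 2.5)  # dist((0,0),(3,4))/2
  cal <- calibration(0.2)
  expect_equal(circumscribed_radius(i3, cal)[["radius_cm"]], 0.5)
})

test_that("radius equals the brute-force farthest contour pair on random blobs", {
  for (s in 1:25) {
    m <- random_blob(seed = s)
    inst <- instance_from_mask(m)
    r <- circumscribed_radius(inst)[["radius_px"]]
    expect_equal(r, brute_diameter(unique(inst$contour)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("half-diameter and minimal enclosing circle obey the Jung bound", {
  for (s in 1:15) {
    m <- random_blob(seed = 100 + s)
    inst <- instance_from_mask(m)
    r <- circumscribed_radius(inst)[["radius_px"]]
    rmec <- brute_mec_radius(unique(inst$contour))
    expect_gte(rmec + 1e-9, r)
    expect_lte(rmec, r * 2 / sqrt(3) + 1e-9)
  }
})

test_that("aspect ratio is the bounding-box extent ratio", {
  m <- matrix(0L, 20, 20)
  m[5:9, 3:12] <- 1L  # 5 rows x 10 cols
  expect_equal(aspect_ratio(instance_from_mask(m)), 2)
  sq <- matrix(0L, 9, 9); sq[2:7, 3:8] <- 1L
  expect_equal(aspect_ratio(instance_from_mask(sq)), 1)
  for (s in 1:10) {
    mb <- random_blob(seed = 200 + s)
    inst <- instance_from_mask(mb)
    idx <- which(mb == 1L, arr.ind = TRUE)
    expect_equal(aspect_ratio(inst),
                 (diff(range(idx[, 2])) + 1) / (diff(range(idx[, 1])) + 1))
  }
})

test_that("coverage counts pixels and converts with the squared calibration", {
  m <- matrix(0L, 10, 10); m[2:6, 3:7] <- 1L
  inst <- instance_from_mask(m)
  cv <- coverage(inst, calibration(0.2))
  expect_equal(cv[["coverage_px"]], 25)
  expect_equal(cv[["coverage_cm2"]], 1.0)
  full <- matrix(1L, 7, 9)
  expect_equal(coverage(instance_from_mask(full))[["coverage_px"]], 63)
  for (s in 1:10) {
    mb <- random_blob(seed = 300 + s)
    tot <- 0
    for (i in seq_len(nrow(mb))) for (j in seq_len(ncol(mb)))
      tot <- tot + mb[i, j]
    expect_equal(coverage(instance_from_mask(mb))[["coverage_px"]], tot)
  }
})

test_that("the azimuth of collinear pixel sets is exact", {
  mk_line <- function(pts) {
    m <- matrix(0L, 40, 40); m[pts] <- 1L
    instance_from_mask(m)
  }
  diag45 <- cbind(5:20, 5:20)  # row = col: 45 degrees to the x-axis
  a <- azimuth_angle(mk_line(diag45))
  expect_equal(a$beta_deg, 45, tolerance = 1e-9)
  expect_true(a$ok)
  horiz <- cbind(rep(10L, 16), 5:20)  # along x-axis
  expect_equal(azimuth_angle(mk_line(horiz))$beta_deg, 0, tolerance = 1e-9)
  vert <- cbind(5:20, rep(10L, 16))   # perpendicular
  expect_equal(azimuth_angle(mk_line(vert))$beta_deg, 90, tolerance = 1e-9)
  # y-axis reference flips the two axis cases
  expect_equal(azimuth_angle(mk_line(horiz), north_axis = "y")$beta_deg, 90,
               tolerance = 1e-9)
})

test_that("isotropic instances are flagged ill-conditioned, not errored", {
  sq <- matrix(0L, 12, 12); sq[3:9, 3:9] <- 1L
  a <- azimuth_angle(instance_from_mask(sq))
  expect_false(a$ok)
  expect_true(is.finite(a$beta_deg))
  expect_lt(a$anisotropy, 1.2)
})

test_that("color features average RGB and HSV over the instance", {
  m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L
  inst <- instance_from_mask(m)
  img <- array(0, c(8, 8, 3))
  img[, , 1] <- 0.2; img[, , 2] <- 0.6; img[, , 3] <- 0.1
  cf <- color_features(img, inst)
  expect_equal(unname(cf$rgb_mean), c(0.2, 0.6, 0.1))
  blue <- array(0, c(8, 8, 3)); blue[, , 3] <- 1
  cb <- color_features(blue, inst)
  expect_equal(unname(cb$hsv_mean), c(240, 1, 1))
  gray <- array(0.5, c(8, 8, 3))
  expect_equal(color_features(gray, inst)$hsv_mean[["s"]], 0)
})

test_that("hue averaging is circular across the 0/360 wrap", {
  m <- matrix(0L, 2, 2); m[1, 1] <- 1L; m[2, 1] <- 1L
  inst <- instance_from_mask(m)
  img <- array(0, c(2, 2, 3))
  # hues 350 and 10 degrees: circular mean 0, plain mean 180
  col1 <- grDevices::col2rgb(grDevices::hsv(350 / 360, 1, 1)) / 255
  col2 <- grDevices::col2rgb(grDevices::hsv(10 / 360, 1, 1)) / 255
  for (ch in 1:3) { img[1, 1, ch] <- col1[ch]; img[2, 1, ch] <- col2[ch] }
  h <- color_features(img, inst)$hsv_mean[["h"]]
  expect_true(h < 1 || h > 359)
  h_plain <- color_features(img, inst, circular_hue = FALSE)$hsv_mean[["h"]]
  expect_equal(h_plain, 180, tolerance = 0.5)
})

test_that("the full trait table composes the per-trait functions", {
  m <- matrix(0L, 24, 24); m[5:14, 8:17] <- 1L
  img <- array(0.3, c(24, 24, 3)); img[, , 2] <- 0.7
  ph <- phenotype_image(img, m, cal = calibration(0.1), min_area = 5)
  expect_equal(nrow(ph), 1)
  inst <- instance_from_mask(m)
  expect_equal(ph$coverage_px, 100)
  expect_equal(ph$coverage_cm2, 1.0)
  expect_equal(ph$radius_px, circumscribed_radius(inst)[["radius_px"]])
  expect_equal(ph$aspect_ratio, 1)
  expect_false(ph$azimuth_ok)  # square blob: isotropic
  expect_equal(ph$g_mean, 0.7)
  # empty mask: empty table with the full header
  e <- phenotype_image(img, matrix(0L, 24, 24))
  expect_equal(nrow(e), 0)
  expect_true(all(c("coverage_px", "radius_px", "azimuth_deg", "h_mean")
                  %in% names(e)))
})

test_that("traits are invariant under translation of the instance", {
  m <- matrix(0L, 40, 40)
  blob <- random_blob(H = 15, W = 15, seed = 77)
  m[3:17, 3:17] <- blob
  m2 <- matrix(0L, 40, 40)
  m2[20:34, 15:29] <- blob
  img <- array(0.4, c(40, 40, 3))
  a <- phenotype_image(img, m, min_area = 1)
  b <- phenotype_image(img, m2, min_area = 1)
  for (tr in c("coverage_px", "radius_px", "aspect_ratio", "azimuth_deg"))
    expect_equal(a[[tr]], b[[tr]], tolerance = 1e-9, label = tr)
  expect_false(isTRUE(all.equal(a$row, b$row)))
})

test_that("instance coverages sum to the mask total when min_area is 1", {
  set.seed(5)
  m <- matrix(rbinom(900, 1, 0.25), 30, 30)
  inst <- label_plants(m, min_area = 1)
  expect_equal(sum(vapply(inst, function(i) nrow(i$pixels), numeric(1))),
               sum(m))
})
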