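test_that("TIFF load/write round-trips pixel arrays losslessly", {
  d <- withr::local_tempdir()
  m8 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  p8 <- file.path(d, "g8.tif")
  write_plane(m8, p8, 8)
  ld <- load_image(p8)
  expect_equal(ld$bit_depth, 8)
  expect_identical(ld$planes[[1]], m8)

  m16 <- matrix(sample(0:65535, 400, replace = TRUE), 20, 20)
  p16 <- file.path(d, "g16.tif")
  write_plane(m16, p16, 16)
  ld16 <- load_image(p16)
  expect_equal(ld16$bit_depth, 16)
  expect_identical(ld16$planes[[1]], m16)

  # RGB splits into 3 planes in R,G,B order
  vals <- array(sample(0:255, 300, replace = TRUE), c(10, 10, 3))
  prgb <- file.path(d, "rgb.tif")
  tiff::writeTIFF(vals / 255, prgb, bits.per.sample = 8)
  ldr <- load_image(prgb)
  expect_length(ldr$planes, 3)
  expect_equal(ldr$planes[[2]], matrix(as.integer(vals[, , 2]), 10, 10))
})

test_that("z-stacks, >3 channels and missing files are rejected", {
  d <- withr::local_tempdir()
  pz <- file.path(d, "stack.tif")
  tiff::writeTIFF(list(matrix(0.5, 5, 5), matrix(0.2, 5, 5)), pz,
                  bits.per.sample = 8)
  expect_error(load_image(pz), "single-plane")
  p4 <- file.path(d, "rgba.tif")
  suppressWarnings(tiff::writeTIFF(array(runif(100), c(5, 5, 4)), p4,
                                   bits.per.sample = 8))
  suppressWarnings(expect_error(load_image(p4), "3 channels"))  # libtiff chatter
  expect_error(load_image(file.path(d, "nope.tif")), "not found")
})

test_that("channel matching enforces roles and discards unmapped planes", {
  d <- withr::local_tempdir()
  arr <- array(runif(300), c(10, 10, 3))
  p <- file.path(d, "rgb.tif")
  tiff::writeTIFF(arr, p, bits.per.sample = 8)
  ld <- load_image(p)
  mk <- match_channels(ld, list(MarkerI = 0, MarkerII = 1, MarkerIII = 2))
  expect_named(mk, c("MarkerI", "MarkerII", "MarkerIII"))
  expect_equal(mk$MarkerI$role, "MarkerI")
  mk1 <- match_channels(ld, list(MarkerI = 2))
  expect_named(mk1, "MarkerI")
  expect_identical(mk1$MarkerI$pixels, ld$planes[[3]])
  expect_error(match_channels(ld, list(MarkerII = 0)), "MarkerI")
  expect_error(match_channels(ld, list(MarkerI = 0, MarkerI = 1)), "duplicate")
})

test_that("ROI crop reports centroids in original image coordinates", {
  sc <- generate_scene(n_cells = 8, seed = 42, width = 300, height = 260,
                       intensity = list(background = 10,
                                        cell_value = c(200, 200), noise_sd = 0))
  m1 <- marker_image(sc$markers$MarkerI, "MarkerI")
  full <- label_cells(binarize(m1, 100))
  tb_full <- marker1_features(full, m1)

  roi <- roi_shape("rectangle", dim(m1$pixels), x = 100, y = 50,
                   width = 180, height = 190)
  cr <- crop_to_roi(list(MarkerI = m1), roi)
  expect_equal(unname(cr$offset), c(100, 50))
  lm <- label_cells(binarize(cr$markers$MarkerI, 100), cr$offset)
  tb_roi <- marker1_features(lm, cr$markers$MarkerI)

  # cells fully inside the ROI keep their original-coordinate centroids
  inside <- dplyr::filter(
    tb_full, .data$M1.bbox_x >= 100, .data$M1.bbox_y >= 50,
    .data$M1.bbox_x + .data$M1.bbox_w <= 280,
    .data$M1.bbox_y + .data$M1.bbox_h <= 240)
  expect_gt(nrow(inside), 0)
  for (i in seq_len(nrow(inside))) {
    j <- which.min((tb_roi$M1.centroid_x - inside$M1.centroid_x[i])^2 +
                   (tb_roi$M1.centroid_y - inside$M1.centroid_y[i])^2)
    expect_equal(tb_roi$M1.centroid_x[j], inside$M1.centroid_x[i])
    expect_equal(tb_roi$M1.centroid_y[j], inside$M1.centroid_y[i])
    expect_equal(tb_roi$M1.area_px[j], inside$M1.area_px[i])
  }

  # full-image ROI is the identity
  roi_full <- roi_shape("none", dim(m1$pixels))
  cr2 <- crop_to_roi(list(MarkerI = m1), roi_full)
  expect_identical(cr2$markers$MarkerI$pixels, m1$pixels)
  expect_equal(unname(cr2$offset), c(0, 0))
})

test_that("degenerate ROIs are rejected", {
  expect_error(roi_shape("rectangle", c(50, 50), x = 60, y = 60,
                         width = 5, height = 5), "no interior")
  r <- roi_shape("ellipse", c(50, 50), x = 25, y = 25, width = 20, height = 12)
  r$closed <- FALSE
  m <- marker_image(matrix(0L, 50, 50), "MarkerI")
  expect_error(crop_to_roi(list(MarkerI = m), r), "closed")
})

test_that("channel histogram conserves counts and rescales 16-bit to 256 bins", {
  m <- marker_image(matrix(7L, 10, 10), "MarkerI")
  h <- channel_histogram(m)
  expect_equal(h[8], 100)           # all mass in bin 7
  expect_equal(sum(h), 100)

  v <- matrix(sample(0:65535, 400, replace = TRUE), 20, 20)
  v[1] <- 65535L
  h16 <- channel_histogram(marker_image(v, "MarkerI", bit_depth = 16))
  expect_equal(sum(h16), 400)
  expect_gt(h16[256], 0)            # max value maps to bin 255
  # round-half-up rescale oracle
  expect_equal(h16, tabulate(floor(v * 255 / 65535 + 0.5) + 1, 256))
})

test_that("calibration scales lengths by pixel width and areas by the product", {
  sc <- generate_scene(n_cells = 5, seed = 9,
                       intensity = list(background = 10,
                                        cell_value = c(200, 200), noise_sd = 0))
  px <- sc$markers$MarkerI
  m_uncal <- marker_image(px, "MarkerI")
  m_cal <- marker_image(px, "MarkerI", calibration = calibration(0.5, 0.25, "um"))
  lm <- label_cells(binarize(m_uncal, 100))
  t1 <- marker1_features(lm, m_uncal)
  t2 <- marker1_features(lm, m_cal)
  expect_equal(t2$M1.area, t1$M1.area * 0.5 * 0.25)
  for (f in c("M1.perimeter", "M1.feret_max", "M1.feret_min",
              "M1.ellipse_major", "M1.ellipse_minor"))
    expect_equal(t2[[f]], t1[[f]] * 0.5)
  for (f in c("M1.circularity", "M1.roundness", "M1.aspect_ratio",
              "M1.solidity", "M1.centroid_x", "M1.centroid_y"))
    expect_equal(t2[[f]], t1[[f]])
})
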