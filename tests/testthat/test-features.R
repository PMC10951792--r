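feature_table_for <- function(scene, cal = calibration()) {
  m1 <- marker_image(scene$markers$MarkerI, "MarkerI", calibration = cal)
  lm <- label_cells(binarize(m1, 100))
  marker1_features(lm, m1)
}

test_that("a rasterized disk has near-unit circularity and high solidity", {
  sc <- generate_scene(n_cells = 1, seed = 4, width = 64, height = 64,
                       shape = list(radius = c(20, 20), aspect = c(1, 1)),
                       intensity = list(background = 10,
                                        cell_value = c(200, 200), noise_sd = 0))
  tb <- feature_table_for(sc)
  expect_gte(tb$M1.circularity, 0.88)
  expect_lte(tb$M1.circularity, 1)
  expect_gte(tb$M1.solidity, 0.95)
  expect_equal(tb$M1.roundness, 1, tolerance = 0.05)
})

test_that("a thin bar is extremely elongated and non-circular", {
  px <- matrix(0L, 20, 60)
  px[10, 6:55] <- 200L            # 1 x 50 bar
  m <- marker_image(px, "MarkerI")
  lm <- label_cells(binarize(m, 100))
  tb <- marker1_features(lm, m)
  expect_gt(tb$M1.aspect_ratio, 20)
  expect_lt(tb$M1.circularity, 0.1)
  # closed-form: 102 crack edges, 4 corners, each corrected by (2-sqrt(2))/2
  expect_equal(celltyper:::crack_perimeter(lm$contours[[1]]),
               102 - 4 * (2 - sqrt(2)) / 2)
})

test_that("intensity statistics match hand-computed values", {
  px <- matrix(0L, 4, 4)
  px[1, 1] <- 1L; px[1, 2] <- 2L; px[2, 1] <- 3L; px[2, 2] <- 10L
  f <- intensity_features(c(1, 2, 3, 10), calibrated_area = 4)
  expect_equal(f$mean, 4)
  expect_equal(f$median, 2.5)
  expect_equal(f$std, sqrt(12.5))          # population sd
  expect_equal(f$min, 1); expect_equal(f$max, 10)
  expect_equal(f$raw_integrated_density, 16)
  expect_equal(f$integrated_density, 16)   # mean * area = 4 * 4
  # constant region: zero spread, moments conventionally 0
  fc <- intensity_features(rep(7, 9), 9)
  expect_equal(fc$mean, 7); expect_equal(fc$median, 7)
  expect_equal(fc$std, 0); expect_equal(fc$skewness, 0)
  expect_equal(fc$kurtosis, 0)
  # mode is the lowest among ties
  ft <- intensity_features(c(5, 5, 9, 9, 1), 5)
  expect_equal(ft$mode, 5)
  expect_error(intensity_features(numeric(0), 0), "empty region")
})

test_that("feature invariants hold across randomized scenes", {
  withr::local_seed(99)
  for (k in 1:5) {
    sc <- generate_scene(n_cells = sample(5:12, 1), seed = 400 + k,
                         shape = list(radius = c(4, 14), aspect = c(1, 3)),
                         intensity = list(background = 10,
                                          cell_value = c(120, 230),
                                          noise_sd = 3))
    m1 <- marker_image(sc$markers$MarkerI, "MarkerI")
    lm <- label_cells(binarize(m1, 60))
    tb <- marker1_features(lm, m1)
    expect_true(all(tb$M1.area > 0))
    expect_true(all(tb$M1.circularity > 0 & tb$M1.circularity <= 1))
    expect_true(all(tb$M1.solidity > 0 & tb$M1.solidity <= 1))
    expect_true(all(tb$M1.aspect_ratio >= 1))
    expect_true(all(tb$M1.min <= tb$M1.median & tb$M1.median <= tb$M1.max))
    expect_equal(tb$M1.integrated_density, tb$M1.mean * tb$M1.area)
    expect_equal(tb$M1.raw_integrated_density, tb$M1.mean * tb$M1.area_px)
  }
})

test_that("dimensionless shape features are stable under 90-degree rotation", {
  px <- matrix(0L, 80, 80)
  g <- expand.grid(r = 1:80, c = 1:80)
  inside <- ((g$c - 40) / 22)^2 + ((g$r - 40) / 9)^2 <= 1
  px[cbind(g$r[inside], g$c[inside])] <- 200L
  m <- marker_image(px, "MarkerI")
  t1 <- marker1_features(label_cells(binarize(m, 100)), m)
  m2 <- marker_image(t(px), "MarkerI")    # 90-degree rotation (+ flip)
  t2 <- marker1_features(label_cells(binarize(m2, 100)), m2)
  for (f in c("M1.circularity", "M1.roundness", "M1.aspect_ratio", "M1.solidity"))
    expect_lt(abs(t1[[f]] - t2[[f]]) / t1[[f]], 0.05)
})

test_that("summaries use type-7 quantiles and sample variance", {
  tb <- tibble::tibble(cell_id = 1:100, M1.area = as.numeric(1:100),
                       relevant = TRUE, cell_type = NA_character_)
  s <- summarize_features(tb)
  r <- s[s$feature == "M1.area", ]
  expect_equal(r$Q1, 25.75)
  expect_equal(r$Q3, 75.25)
  expect_equal(r$IQR, r$Q3 - r$Q1)
  expect_equal(r$variance, stats::var(1:100))
  expect_true(r$min <= r$Q1 && r$Q1 <= r$Q2 && r$Q2 <= r$Q3 && r$Q3 <= r$max)
  # constant column and single-row table degenerate gracefully
  s2 <- summarize_features(tibble::tibble(M1.x = rep(3, 5)))
  expect_equal(s2$variance, 0); expect_equal(s2$IQR, 0)
  s3 <- summarize_features(tibble::tibble(M1.x = 42))
  expect_equal(s3$mean, s3$median)
  expect_error(summarize_features(tibble::tibble(M1.x = numeric(0))), "empty")
})
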