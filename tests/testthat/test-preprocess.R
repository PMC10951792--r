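flat_marker <- function(value = 50, n = 32) {
  marker_image(matrix(as.integer(value), n, n), "MarkerI")
}

test_that("empty chain is the identity and steps preserve shape and depth", {
  m <- flat_marker()
  out <- apply_chain(m, list())
  expect_identical(out$pixels, m$pixels)
  steps <- list(preprocess_step("gaussian_blur", sigma = 2),
                preprocess_step("median_filter", radius = 1),
                preprocess_step("mean_filter", radius = 2),
                preprocess_step("subtract_background", radius = 5),
                preprocess_step("enhance_contrast", saturation = 0.01),
                preprocess_step("invert"),
                preprocess_step("gamma_correction", gamma = 0.5))
  sc <- generate_scene(n_cells = 6, seed = 2,
                       intensity = list(background = 20,
                                        cell_value = c(150, 220), noise_sd = 5))
  img <- marker_image(sc$markers$MarkerI, "MarkerI")
  for (s in steps) {
    out <- apply_chain(img, list(s))
    expect_identical(dim(out$pixels), dim(img$pixels))
    expect_equal(out$bit_depth, img$bit_depth)
    expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  }
})

test_that("blurring a constant image returns the same constant", {
  m <- flat_marker(81)
  out <- apply_chain(m, list(preprocess_step("gaussian_blur", sigma = 2)))
  expect_identical(out$pixels, m$pixels)
})

test_that("median filter removes an isolated outlier", {
  px <- matrix(40L, 15, 15)
  px[8, 8] <- 255L
  out <- apply_chain(marker_image(px, "MarkerI"),
                     list(preprocess_step("median_filter", radius = 1)))
  expect_equal(out$pixels[8, 8], 40)   # 3x3 median of {40 x8, 255} is 40
})

test_that("linear smoothing filters preserve the global mean within 1%", {
  sc <- generate_scene(n_cells = 10, seed = 5,
                       intensity = list(background = 30,
                                        cell_value = c(120, 200), noise_sd = 4))
  img <- marker_image(sc$markers$MarkerI, "MarkerI")
  for (s in list(preprocess_step("gaussian_blur", sigma = 2),
                 preprocess_step("mean_filter", radius = 2))) {
    out <- apply_chain(img, list(s))
    expect_lt(abs(mean(out$pixels) - mean(img$pixels)) / mean(img$pixels), 0.01)
  }
})

test_that("invert twice is the identity for 8-bit images", {
  px <- matrix(sample(0:255, 30 * 30, replace = TRUE), 30, 30)
  img <- marker_image(px, "MarkerI")
  out <- apply_chain(img, list(preprocess_step("invert"),
                               preprocess_step("invert")))
  expect_identical(out$pixels, px)
})

test_that("subtract_background flattens a bright plateau toward zero", {
  px <- matrix(100L, 40, 40)
  px[10:30, 10:30] <- 180L   # broad plateau wider than the ball
  out <- apply_chain(marker_image(px, "MarkerI"),
                     list(preprocess_step("subtract_background", radius = 4)))
  # broad structures are background: mostly removed
  expect_lt(mean(out$pixels[15:25, 15:25]), 10)
})

test_that("bad steps fail fast naming the step", {
  m <- flat_marker()
  expect_error(preprocess_step("sharpen"), "unknown preprocessing op")
  expect_error(apply_chain(m, list(preprocess_step("gaussian_blur", sigma = -1))),
               "step 1")
  expect_error(apply_chain(m, list(preprocess_step("invert"),
                                   preprocess_step("median_filter", radius = 0))),
               "step 2")
})
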