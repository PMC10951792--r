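test_that("scenes are reproducible from their seed and honour ground truth", {
  a <- generate_scene(n_cells = 12, seed = 77)
  b <- generate_scene(n_cells = 12, seed = 77)
  expect_identical(a$markers$MarkerI, b$markers$MarkerI)
  expect_identical(a$truth$cx, b$truth$cx)
  z <- generate_scene(n_cells = 0, seed = 1, width = 64, height = 64)
  expect_equal(unique(as.vector(z$markers$MarkerI)), 10)
  expect_equal(nrow(z$truth), 0)
  # pixel sets are mutually disjoint without requested overlap
  sc <- generate_scene(n_cells = 15, seed = 5)
  all_px <- unlist(sc$truth$pixels)
  expect_equal(anyDuplicated(all_px), 0)
})

test_that("noiseless nuclei binarize to exactly the planted pixel set", {
  args <- preset("nuclei")
  args$intensity$noise_sd <- 0
  sc <- do.call(generate_scene, c(list(n_cells = 50, seed = 1), args))
  m <- marker_image(sc$markers$MarkerI, "MarkerI")
  t <- auto_threshold(channel_histogram(m), "Otsu")
  expect_identical(which(binarize(m, t)), sort(unlist(sc$truth$pixels)))
  expect_equal(label_cells(binarize(m, t))$n_cells, 50)
})

test_that("infeasible packings fail with a clear error", {
  expect_error(generate_scene(n_cells = 60, seed = 1, width = 96, height = 96,
                              shape = list(radius = c(12, 14), aspect = c(1, 1))),
               "infeasible packing")
})

test_that("the spirochete preset represents all five classes with ordered geometry", {
  sc <- do.call(generate_scene, c(list(n_cells = 40, seed = 6), preset("spirochete")))
  expect_setequal(unique(sc$truth$class), c("BC", "R", "E", "S", "N"))
  expect_equal(as.vector(table(sc$truth$class)[c("BC", "R", "E", "S", "N")]),
               c(4, 6, 6, 10, 14))
  # intended strict area ordering: S < {R, N} < E < BC
  ar <- split(sc$truth$area_px, sc$truth$class)
  expect_lt(max(ar$S), min(c(ar$R, ar$N)))
  expect_lt(max(c(ar$R, ar$N)), min(ar$E))
  expect_lt(max(ar$E), min(ar$BC))
})

test_that("end-to-end count and area recovery on low-noise scenes", {
  ok_cells <- 0; total <- 0
  for (s in 1:5) {
    sc <- do.call(generate_scene, c(list(n_cells = 20, seed = 500 + s),
                                    preset("nuclei")))
    m <- marker_image(sc$markers$MarkerI, "MarkerI")
    t <- auto_threshold(channel_histogram(m), "Otsu")
    lm <- label_cells(binarize(m, t))
    expect_equal(lm$n_cells, 20)
    tb <- marker1_features(lm, m)
    tr <- sc$truth
    for (i in seq_len(nrow(tb))) {
      j <- which.min((tr$cx - tb$M1.centroid_x[i])^2 +
                     (tr$cy - tb$M1.centroid_y[i])^2)
      total <- total + 1
      if (abs(tb$M1.area_px[i] - tr$area_px[j]) / tr$area_px[j] <= 0.05)
        ok_cells <- ok_cells + 1
    }
  }
  expect_gte(ok_cells / total, 0.99)
})

test_that("scene files load back into the pipeline", {
  d <- withr::local_tempdir()
  sc <- do.call(generate_scene, c(list(n_cells = 6, seed = 9), preset("foci")))
  p <- write_scene(sc, d, "sc")
  ld <- load_image(p)
  expect_length(ld$planes, 3)
  expect_identical(ld$planes[[1]], sc$markers$MarkerI)
  expect_identical(ld$planes[[2]], sc$markers$MarkerII)
  expect_true(file.exists(file.path(d, "sc_truth.csv")))
  expect_true(file.exists(file.path(d, "sc_foci.csv")))
})
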