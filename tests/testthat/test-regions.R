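scene_labelmap <- function(scene) {
  m1 <- marker_image(scene$markers$MarkerI, "MarkerI")
  list(marker = m1, lm = label_cells(binarize(m1, 100)))
}

test_that("resize obeys monotone containment and erosion approximates a disk", {
  sc <- generate_scene(n_cells = 1, seed = 8, width = 64, height = 64,
                       shape = list(radius = c(10, 10), aspect = c(1, 1)),
                       intensity = list(background = 10,
                                        cell_value = c(200, 200), noise_sd = 0))
  s <- scene_labelmap(sc)
  orig <- cell_pixel_sets(s$lm)[[1]]
  er <- resize_regions(s$lm, resize_spec("erode", 3))[[1]]
  di <- resize_regions(s$lm, resize_spec("dilate", 3))[[1]]
  no <- resize_regions(s$lm, resize_spec("none"))[[1]]
  expect_identical(no, orig)
  expect_true(all(er %in% orig))
  expect_true(all(orig %in% di))
  # disk radius 10 eroded by 3 is close to a disk of radius 7
  expect_equal(length(er), pi * 7^2, tolerance = 0.1)
  expect_equal(length(di), pi * 13^2, tolerance = 0.1)
})

test_that("over-erosion empties a region and measurement flags it missing", {
  px <- matrix(0L, 20, 20)
  px[5:6, 5:6] <- 200L   # 2x2 square
  m1 <- marker_image(px, "MarkerI")
  lm <- label_cells(binarize(m1, 100))
  er <- resize_regions(lm, resize_spec("erode", 2))
  expect_length(er[[1]], 0)
  m2 <- marker_image(px, "MarkerII")
  tab <- measure_marker(lm, m2, resize = resize_spec("erode", 2))
  expect_true(is.na(tab$M2.mean[1]))
})

test_that("dilation never crosses a neighbouring cell's original pixels", {
  px <- matrix(0L, 30, 40)
  px[10:20, 5:15] <- 200L
  px[10:20, 19:29] <- 200L   # 3-px corridor between two squares
  m1 <- marker_image(px, "MarkerI")
  lm <- label_cells(binarize(m1, 100))
  expect_equal(lm$n_cells, 2)
  cells <- cell_pixel_sets(lm)
  di <- resize_regions(lm, resize_spec("dilate", 4))
  expect_length(intersect(di[[1]], cells[[2]]), 0)
  expect_length(intersect(di[[2]], cells[[1]]), 0)
  # contested corridor pixels split by nearest original region: no overlap
  expect_length(intersect(di[[1]], di[[2]]), 0)
  # corridor columns nearer square 1 go to cell 1
  got_cols <- sort(unique((setdiff(di[[1]], cells[[1]]) - 1L) %/% 30 + 1L))
  expect_true(all(got_cols <= 17))
})

test_that("planted foci are recovered and counts are monotone in tolerance", {
  sc <- do.call(generate_scene, c(list(n_cells = 25, seed = 31), preset("foci")))
  m1 <- marker_image(sc$markers$MarkerI, "MarkerI")
  m2 <- marker_image(sc$markers$MarkerII, "MarkerII")
  lm <- label_cells(binarize(m1, auto_threshold(channel_histogram(m1), "Otsu")))
  expect_equal(lm$n_cells, 25)
  cells <- cell_pixel_sets(lm)
  tb <- marker1_features(lm, m1)
  tr <- sc$truth
  hits <- 0
  for (i in seq_along(cells)) {
    j <- which.min((tr$cx - tb$M1.centroid_x[i])^2 +
                   (tr$cy - tb$M1.centroid_y[i])^2)
    fc <- find_foci(m2, cells[[i]], tolerance = 30)
    if (fc$count == tr$foci_n[j]) hits <- hits + 1
    counts <- vapply(c(5, 15, 30, 60, 120),
                     function(tol) find_foci(m2, cells[[i]], tol)$count,
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  expect_gte(hits / length(cells), 0.99)
})

test_that("prominence semantics match the brute-force oracle", {
  # two spots whose saddle is 5 below the lower peak: one focus at tol 30
  w <- matrix(10, 15, 15)
  w[8, 5] <- 120; w[8, 8] <- 110
  w[8, 6] <- 105; w[8, 7] <- 105       # shallow saddle (5 below 110)
  m <- marker_image(w, "MarkerII")
  region <- which(w >= 0)
  expect_equal(find_foci(m, region, tolerance = 30)$count, 1)
  expect_equal(find_foci(m, region, tolerance = 4)$count, 2)
  expect_equal(oracle_foci_count(w, 30), 1)
  expect_equal(oracle_foci_count(w, 4), 2)
  # flat region: no maxima
  flat <- marker_image(matrix(42, 9, 9), "MarkerII")
  expect_equal(find_foci(flat, 1:81, tolerance = 30)$count, 0)
  # randomized windows against the oracle
  withr::local_seed(555)
  for (k in 1:25) {
    ww <- matrix(sample(0:80, 100, replace = TRUE), 10, 10)
    mk <- marker_image(ww, "MarkerII")
    tol <- sample(c(5, 15, 30), 1)
    expect_equal(find_foci(mk, 1:100, tolerance = tol)$count,
                 oracle_foci_count(ww, tol),
                 info = sprintf("window %d tol %d", k, tol))
  }
})

test_that("secondary-marker measurement gates foci and mirrors identical planes", {
  sc <- generate_scene(n_cells = 8, seed = 12,
                       intensity = list(background = 10,
                                        cell_value = c(150, 220), noise_sd = 0))
  m1 <- marker_image(sc$markers$MarkerI, "MarkerI")
  lm <- label_cells(binarize(m1, 80))
  m2 <- marker_image(sc$markers$MarkerI, "MarkerII")  # same plane as Marker I
  tb1 <- marker1_features(lm, m1)
  tb2 <- measure_marker(lm, m2, resize = resize_spec("none"))
  expect_equal(tb2$M2.mean, tb1$M1.mean)
  expect_false("M2.foci_count" %in% names(tb2))
  tb2f <- measure_marker(lm, m2, foci_enabled = TRUE)
  expect_true("M2.foci_count" %in% names(tb2f))
  # dilation into the dark surround lowers the mean
  tb2d <- measure_marker(lm, m2, resize = resize_spec("dilate", 3))
  expect_true(all(tb2d$M2.mean < tb2$M2.mean))
  expect_error(measure_marker(lm, m1), "Markers II/III")
})
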