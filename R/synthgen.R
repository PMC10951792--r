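#' Generate a synthetic multi-channel fluorescence scene
#'
#' Renders elliptical "cells" on a dark background across up to three marker
#' planes, with exhaustive ground truth (per-cell centre, axes, pixel set,
#' intensities, planted foci and intended class), so that every pipeline
#' stage can be validated without external data. All randomness flows from
#' the single `seed`; regenerating with the same arguments reproduces the
#' scene exactly. Noise is additive Gaussian, clipped to the bit range.
#'
#' Cells are placed by rejection sampling with a minimum separation `gap`
#' between bounding circles; `overlap_fraction > 0` deliberately places that
#' fraction of cells as fused pairs (centres at 75% of the sum of their
#' bounding radii) to exercise watershed splitting.
#'
#' @param n_cells Number of cells (>= 0).
#' @param seed Integer seed.
#' @param width,height Scene size in pixels; defaults to a square sized for
#'   a packing density of about 0.22 (at least 192 px).
#' @param shape List: `radius` range of the semi-minor axis and `aspect`
#'   range (major/minor; 1 = disk). Ignored when `classes` is given.
#' @param classes Optional per-class geometry: tibble with columns `class`,
#'   `prop`, `radius_min`, `radius_max`, `aspect_min`, `aspect_max`
#'   (proportions are realized exactly by largest remainder).
#' @param intensity List: `background` level, `cell_value` range on Marker I,
#'   `noise_sd` of the additive Gaussian noise (applied to every plane).
#' @param marker2 Optional list describing the Marker II plane: `base` range
#'   of per-cell intensity and `base_mode` (`"uniform"`, or `"binary"` to
#'   pick one endpoint at random, giving a clean high/low split).
#' @param foci Optional list (requires `marker2`): `count` range of planted
#'   spots per cell, `amplitude`, `sigma`, `min_sep` (centre separation, px).
#' @param marker3 Optional list like `marker2`.
#' @param overlap_fraction Fraction of cells placed as fused pairs.
#' @param gap Minimum separation between non-fused cells (px).
#' @param bit_depth 8 or 16.
#' @return A `ct_scene`: `markers` (named list of intensity matrices),
#'   `truth` (tibble with a `pixels` list-column of linear indices and a
#'   `foci` list-column of spot coordinates), `seed`, `dim`.
#' @export
generate_scene <- function(n_cells = 50, seed = 1,
                           width = NULL, height = NULL,
                           shape = list(radius = c(8, 16), aspect = c(1, 1)),
                           classes = NULL,
                           intensity = list(background = 10,
                                            cell_value = c(180, 220),
                                            noise_sd = 0),
                           marker2 = NULL, foci = NULL, marker3 = NULL,
                           overlap_fraction = 0, gap = 4, bit_depth = 8) {
  stopifnot(n_cells >= 0, bit_depth %in% c(8, 16))
  withr::with_seed(seed, generate_scene_impl(
    n_cells, width, height, shape, classes, intensity, marker2, foci, marker3,
    overlap_fraction, gap, bit_depth, seed))
}

generate_scene_impl <- function(n_cells, width, height, shape, classes,
                                intensity, marker2, foci, marker3,
                                overlap_fraction, gap, bit_depth, seed) {
  # per-cell geometry
  if (!is.null(classes)) {
    counts <- largest_remainder(classes$prop, n_cells)
    cls <- rep(classes$class, counts)
    if (n_cells > 0) cls <- sample(cls)
    gi <- match(cls, classes$class)
    b <- stats::runif(n_cells, classes$radius_min[gi], classes$radius_max[gi])
    asp <- stats::runif(n_cells, classes$aspect_min[gi], classes$aspect_max[gi])
  } else {
    cls <- rep(NA_character_, n_cells)
    b <- stats::runif(n_cells, shape$radius[1], shape$radius[2])
    asp <- stats::runif(n_cells, shape$aspect[1], shape$aspect[2])
  }
  a <- b * asp
  theta <- stats::runif(n_cells, 0, pi)
  # scene size from packing density ~0.22 on bounding circles
  if (is.null(width)) {
    need <- sum((a + gap)^2 * pi)
    width <- max(192L, as.integer(ceiling(sqrt(need / 0.22))))
  }
  if (is.null(height)) height <- width
  placed <- place_cells(a, width, height, gap, overlap_fraction)

  maxv <- max_intensity(bit_depth)
  bg <- intensity$background
  m1_value <- stats::runif(n_cells, intensity$cell_value[1], intensity$cell_value[2])
  planes <- list(MarkerI = matrix(bg, height, width))
  draw_base <- function(model) {
    if (is.null(model)) return(NULL)
    base <- if (identical(model$base_mode, "binary")) {
      model$base[1 + (stats::runif(n_cells) > 0.5)]
    } else {
      stats::runif(n_cells, model$base[1], model$base[2])
    }
    base
  }
  m2_base <- draw_base(marker2)
  m3_base <- draw_base(marker3)
  if (!is.null(marker2)) planes$MarkerII <- matrix(bg, height, width)
  if (!is.null(marker3)) planes$MarkerIII <- matrix(bg, height, width)

  pixel_sets <- vector("list", n_cells)
  foci_list <- vector("list", n_cells)
  foci_n <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    idx <- ellipse_pixels(placed$cx[i], placed$cy[i], a[i], b[i], theta[i],
                          width, height)
    pixel_sets[[i]] <- idx
    planes$MarkerI[idx] <- m1_value[i]
    if (!is.null(marker2)) planes$MarkerII[idx] <- m2_base[i]
    if (!is.null(marker3)) planes$MarkerIII[idx] <- m3_base[i]
    foci_list[[i]] <- tibble::tibble(x = numeric(0), y = numeric(0))
  }
  if (!is.null(foci)) {
    stopifnot(!is.null(marker2))
    for (i in seq_len(n_cells)) {
      k <- sample(foci$count[1]:foci$count[2], 1)
      pts <- place_foci(k, placed$cx[i], placed$cy[i], a[i], b[i], theta[i],
                        foci$min_sep, margin = 2 + 2 * foci$sigma)
      foci_n[i] <- nrow(pts)
      foci_list[[i]] <- pts
      planes$MarkerII <- add_spots(planes$MarkerII, pts, foci$amplitude,
                                   foci$sigma)
    }
  }
  planes <- lapply(planes, function(p) {
    if (intensity$noise_sd > 0)
      p <- p + stats::rnorm(length(p), 0, intensity$noise_sd)
    matrix(pmin(pmax(as.integer(floor(p + 0.5)), 0L), as.integer(maxv)),
           height, width)
  })
  truth <- tibble::tibble(
    cell = seq_len(n_cells), class = cls,
    cx = placed$cx, cy = placed$cy, a = a, b = b, theta = theta,
    pair = placed$pair,
    m1_value = m1_value,
    m2_base = if (is.null(m2_base)) NA_real_ else m2_base,
    m3_base = if (is.null(m3_base)) NA_real_ else m3_base,
    foci_n = foci_n,
    area_px = lengths(pixel_sets),
    pixels = pixel_sets, foci = foci_list)
  structure(list(markers = planes, truth = truth, seed = seed,
                 dim = c(height, width), bit_depth = bit_depth),
            class = "ct_scene")
}

largest_remainder <- function(prop, n) {
  raw <- prop / sum(prop) * n
  out <- floor(raw)
  rem <- n - sum(out)
  if (rem > 0) {
    add <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[add] <- out[add] + 1
  }
  as.integer(out)
}

place_cells <- function(a, width, height, gap, overlap_fraction) {
  n <- length(a)
  cx <- cy <- numeric(n)
  pair <- rep(NA_integer_, n)
  if (n == 0) return(list(cx = cx, cy = cy, pair = pair))
  n_pairs <- floor(overlap_fraction * n / 2)
  partner <- rep(NA_integer_, n)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      partner[2 * p] <- 2 * p - 1     # cell 2p fuses onto cell 2p-1
      pair[c(2 * p - 1, 2 * p)] <- p
    }
  }
  max_try <- 200 * n + 200
  tries <- 0
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1
      if (tries > max_try)
        stop("infeasible packing: could not place ", n, " cells in ",
             width, "x", height, " after ", max_try, " attempts")
      if (!is.na(partner[i])) {
        j <- partner[i]
        d <- 0.75 * (a[i] + a[j])
        ang <- stats::runif(1, 0, 2 * pi)
        x <- cx[j] + d * cos(ang); y <- cy[j] + d * sin(ang)
      } else {
        x <- stats::runif(1, a[i] + 2, width - a[i] - 3)
        y <- stats::runif(1, a[i] + 2, height - a[i] - 3)
      }
      if (x < a[i] + 2 || x > width - a[i] - 3 ||
          y < a[i] + 2 || y > height - a[i] - 3) next
      prev <- seq_len(i - 1)
      prev <- prev[is.na(pair[prev]) | is.na(pair[i]) | pair[prev] != pair[i]]
      if (length(prev) == 0 ||
          all((cx[prev] - x)^2 + (cy[prev] - y)^2 >=
              (a[prev] + a[i] + gap)^2)) {
        cx[i] <- x; cy[i] <- y
        break
      }
    }
  }
  list(cx = cx, cy = cy, pair = pair)
}

# linear indices of the pixels whose centres fall inside the ellipse
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(0, floor(cx - a)); x1 <- min(width - 1, ceiling(cx + a))
  y0 <- max(0, floor(cy - a)); y1 <- min(height - 1, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  u <- (gx - cx) * cos(theta) + (gy - cy) * sin(theta)
  v <- -(gx - cx) * sin(theta) + (gy - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  as.integer(gx[inside] * height + gy[inside] + 1L)  # column-major [row, col]
}

place_foci <- function(k, cx, cy, a, b, theta, min_sep, margin) {
  xs <- numeric(0); ys <- numeric(0)
  ae <- max(a - margin, 1); be <- max(b - margin, 1)
  tries <- 0
  while (length(xs) < k && tries < 400 * max(k, 1)) {
    tries <- tries + 1
    u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
    if (u^2 + v^2 > 1) next
    x <- cx + u * ae * cos(theta) - v * be * sin(theta)
    y <- cy + u * ae * sin(theta) + v * be * cos(theta)
    if (length(xs) == 0 || all((xs - x)^2 + (ys - y)^2 >= min_sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  tibble::tibble(x = round(xs), y = round(ys))
}

add_spots <- function(plane, pts, amplitude, sigma) {
  h <- nrow(plane); w <- ncol(plane)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; y <- pts$y[i]
    xs <- max(0, x - r):min(w - 1, x + r)
    ys <- max(0, y - r):min(h - 1, y + r)
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
    g <- amplitude * exp(-((gx - x)^2 + (gy - y)^2) / (2 * sigma^2))
    idx <- gx * h + gy + 1L
    plane[idx] <- plane[idx] + g
  }
  plane
}

#' @export
print.ct_scene <- function(x, ...) {
  cat(sprintf("<synthetic scene> %d x %d px, %d cell(s), markers: %s (seed %d)\n",
              x$dim[1], x$dim[2], nrow(x$truth),
              paste(names(x$markers), collapse = ", "), x$seed))
  invisible(x)
}

#' Generator presets for the validation scenarios
#'
#' Returns [generate_scene()] arguments for three canonical scenes:
#' \describe{
#'   \item{nuclei}{Round nuclei (radius 8-16 px) at value 180-220 over
#'     background 10, mild noise (sd 3): the basic segmentation scenario. At
#'     `noise_sd = 0` the image is two-level and any sensible threshold
#'     recovers the planted pixel set exactly.}
#'   \item{foci}{Nuclei at constant Marker I value 100 with a Marker II plane
#'     whose per-cell base is either 40 (low) or 160 (high), plus 0-12
#'     planted Gaussian spots (amplitude 100, sigma 1.2, separation >= 5 px).
#'     A cell's intended label is positive iff its Marker II base is high
#'     and it carries at least 8 foci, so the classical "mean above Marker I
#'     and at least eight foci" rule has known truth counts.}
#'   \item{spirochete}{A monochrome dark-field-style scene mixing five
#'     morphological classes — large round blood cells (BC), round (R),
#'     elongated (E), small (S) and normal (N) bacteria — with proportions
#'     0.10/0.15/0.15/0.25/0.35 and geometry chosen so that areas and
#'     circularities of the classes are strictly ordered. With `n_cells`
#'     divisible by 4, quartile-based rules (BC by area threshold 500;
#'     R = circularity in Q4; E = area in Q4; S = area in Q1; N =
#'     interquartile) reproduce the intended classes exactly on noiseless
#'     scenes.}
#' }
#'
#' @param name `"nuclei"`, `"foci"` or `"spirochete"`.
#' @return Named list of arguments for [generate_scene()].
#' @export
preset <- function(name = c("nuclei", "foci", "spirochete")) {
  name <- match.arg(name)
  switch(name,
    nuclei = list(
      shape = list(radius = c(8, 16), aspect = c(1, 1)),
      intensity = list(background = 10, cell_value = c(180, 220), noise_sd = 3)),
    foci = list(
      shape = list(radius = c(12, 16), aspect = c(1, 1)),
      intensity = list(background = 10, cell_value = c(100, 100), noise_sd = 2),
      marker2 = list(base = c(40, 160), base_mode = "binary"),
      foci = list(count = c(0, 12), amplitude = 100, sigma = 1.2, min_sep = 5)),
    spirochete = list(
      classes = tibble::tibble(
        class = c("BC", "R", "E", "S", "N"),
        prop = c(0.10, 0.15, 0.15, 0.25, 0.35),
        radius_min = c(16.0, 6.0, 2.4, 2.0, 3.8),
        radius_max = c(20.0, 7.0, 2.6, 2.6, 4.3),
        aspect_min = c(1.0, 1.0, 10.0, 2.2, 2.2),
        aspect_max = c(1.0, 1.0, 12.0, 2.8, 2.8)),
      intensity = list(background = 10, cell_value = c(170, 210), noise_sd = 0),
      gap = 6))
}

#' Write a synthetic scene to image files plus ground truth
#'
#' One grayscale TIFF for a single-marker scene, or one multi-channel TIFF
#' (channel order Marker I, II, III) otherwise, along with `<stem>_truth.csv`
#' (per-cell geometry, intensities, intended class, foci count) and
#' `<stem>_foci.csv` (planted spot coordinates).
#'
#' @param scene A `ct_scene`.
#' @param dir Output directory.
#' @param stem File name stem.
#' @return Path of the written image, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  maxv <- max_intensity(scene$bit_depth)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  if (length(scene$markers) == 1) {
    tiff::writeTIFF(scene$markers[[1]] / maxv, img_path,
                    bits.per.sample = scene$bit_depth)
  } else {
    arr <- array(0, c(scene$dim[1], scene$dim[2], 3))
    for (i in seq_along(scene$markers)) arr[, , i] <- scene$markers[[i]] / maxv
    tiff::writeTIFF(arr, img_path, bits.per.sample = scene$bit_depth)
  }
  truth_flat <- scene$truth |> dplyr::select(-"pixels", -"foci")
  write_ct_csv(truth_flat, file.path(dir, paste0(stem, "_truth.csv")))
  foci_flat <- scene$truth |>
    dplyr::select("cell", "foci") |>
    tidyr::unnest("foci")
  write_ct_csv(foci_flat, file.path(dir, paste0(stem, "_foci.csv")))
  invisible(img_path)
}
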