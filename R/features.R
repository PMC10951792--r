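role_prefix <- c(MarkerI = "M1", MarkerII = "M2", MarkerIII = "M3")

#' Shape descriptors of one cell
#'
#' Computes the geometric part of a cell's feature vector from its pixel set
#' and crack-boundary contour. Formulas:
#' * `area` = pixel count times `pixel_width * pixel_height`.
#' * `perimeter` = corner-corrected crack-boundary length: unit crack edges
#'   minus `(2 - sqrt(2))/2` per direction change, times `pixel_width`. The
#'   correction makes 45-degree staircases measure `sqrt(2)` per diagonal
#'   step; results are reproducible bit-exactly within this package (exact
#'   parity with any other tool's perimeter is not claimed).
#' * `circularity` = `4 * pi * area / perimeter^2`, clamped to at most 1,
#'   computed in pixel units (dimensionless).
#' * ellipse axes from second central moments of the pixel centres with the
#'   1/12 unit-square term added per pixel; full axes are `4 * sqrt(lambda)`.
#' * `roundness` = `4 * area / (pi * major^2)`; `aspect_ratio` =
#'   `major / minor`; `solidity` = pixel count / convex-hull area, the hull
#'   taken over pixel corners so solidity never exceeds 1.
#' * Feret diameters from rotating calipers on the corner hull.
#'
#' Lengths are calibrated by `pixel_width`, areas by
#' `pixel_width * pixel_height`; centroid and bounding box stay in pixel
#' coordinates (x = column, y = row, 0-based, origin top-left).
#'
#' @param cell_idx Linear indices of the cell's pixels in the label matrix.
#' @param dim Dimensions `c(nrow, ncol)` of the label matrix.
#' @param contour Crack polygon from [label_cells()] (original coordinates).
#' @param calibration A [calibration()].
#' @param offset `c(x0, y0)` ROI offset added to coordinates.
#' @return One-row tibble of shape features (un-namespaced names).
#' @export
shape_features <- function(cell_idx, dim, contour, calibration = celltyper::calibration(),
                           offset = c(x0 = 0, y0 = 0)) {
  if (length(cell_idx) == 0) stop("empty region has no shape features")
  nr <- dim[1]
  x <- (cell_idx - 1L) %/% nr          # 0-based column
  y <- (cell_idx - 1L) %% nr           # 0-based row
  n <- length(cell_idx)
  pw <- calibration$pixel_width; ph <- calibration$pixel_height

  per_px <- crack_perimeter(contour)
  area_px <- n
  circ <- min(1, 4 * pi * area_px / per_px^2)

  # second central moments with the per-pixel unit-square term
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major_px <- 4 * sqrt(max(l1, 0))
  minor_px <- 4 * sqrt(max(l2, 0))
  angle <- (-180 / pi) * atan2(2 * mu11, mu20 - mu02) / 2  # degrees, y-down
  if (angle < 0) angle <- angle + 180

  hull <- pixel_corner_hull(x, y)
  hull_area <- polygon_area(hull)
  feret <- feret_diameters(hull)

  tibble::tibble(
    area = area_px * pw * ph,
    perimeter = per_px * pw,
    circularity = circ,
    roundness = min(1, 4 * area_px / (pi * major_px^2)),
    aspect_ratio = major_px / minor_px,
    solidity = min(1, area_px / hull_area),
    feret_max = feret[1] * pw,
    feret_min = feret[2] * pw,
    ellipse_major = major_px * pw,
    ellipse_minor = minor_px * pw,
    ellipse_angle = angle,
    centroid_x = mx + offset[[1]],
    centroid_y = my + offset[[2]],
    bbox_x = min(x) + offset[[1]],
    bbox_y = min(y) + offset[[2]],
    bbox_w = diff(range(x)) + 1,
    bbox_h = diff(range(y)) + 1,
    area_px = area_px
  )
}

# corner-corrected length of a closed unit-step crack polygon
crack_perimeter <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(4)  # single-pixel fallback (square boundary)
  nxt <- c(2:n, 1)
  dx <- poly[nxt, 1] - poly[, 1]
  dy <- poly[nxt, 2] - poly[, 2]
  prv <- c(n, 1:(n - 1))
  corners <- sum(dx != dx[prv] | dy != dy[prv])
  n - corners * (2 - sqrt(2)) / 2
}

# convex hull over the 4 corners of every pixel (0-based pixel coords)
pixel_corner_hull <- function(x, y) {
  cx <- c(x, x + 1, x, x + 1)
  cy <- c(y, y, y + 1, y + 1)
  pts <- unique(cbind(cx, cy))
  h <- grDevices::chull(pts)
  pts[h, , drop = FALSE]
}

# max and min Feret diameter of a convex polygon (rotating calipers style)
feret_diameters <- function(hull) {
  m <- nrow(hull)
  if (m == 1) return(c(sqrt(2), 1))
  dmax <- max(stats::dist(hull))
  widths <- vapply(seq_len(m), function(i) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(NA_real_)
    # distance of all hull points from the edge's supporting line
    max(abs((hull[, 1] - hull[i, 1]) * e[2] - (hull[, 2] - hull[i, 2]) * e[1]) / len)
  }, numeric(1))
  c(dmax, min(widths, na.rm = TRUE))
}

#' Intensity statistics of one cell on one marker
#'
#' Statistics are computed over the raw intensities of the cell's pixels on
#' the given plane (preprocessing never feeds the measurements). Conventions:
#' population standard deviation; population skewness and excess kurtosis,
#' both 0 for zero-variance regions; mode is the lowest value among tied most
#' frequent intensities; `raw_integrated_density` is the plain sum of pixel
#' values and `integrated_density = mean * calibrated area`.
#'
#' @param values Intensities of the cell's pixels.
#' @param calibrated_area The cell's area in calibrated units.
#' @return One-row tibble of intensity features (un-namespaced names).
#' @export
intensity_features <- function(values, calibrated_area) {
  if (length(values) == 0) stop("empty region has no intensity features")
  v <- as.numeric(values)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  tb <- table(v)
  mode_v <- as.numeric(names(tb)[which.max(tb)])  # which.max: first = lowest value
  tibble::tibble(
    mean = m,
    median = stats::median(v),
    mode = mode_v,
    std = sqrt(m2),
    min = min(v),
    max = max(v),
    integrated_density = m * calibrated_area,
    raw_integrated_density = sum(v),
    skewness = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  )
}

#' Marker I feature table
#'
#' Builds the base feature table: one row per labelled cell with namespaced
#' shape (`M1.area`, `M1.circularity`, ...) and intensity (`M1.mean`, ...)
#' columns, plus `relevant` and `cell_type` placeholders filled by
#' [apply_filters()] and [classify_cells()].
#'
#' @param labelmap A `ct_labelmap` from [label_cells()].
#' @param marker The Marker I [marker_image()] (raw, unpreprocessed plane).
#' @return A tibble with `cell_id` and `M1.*` columns.
#' @export
marker1_features <- function(labelmap, marker) {
  stopifnot(inherits(labelmap, "ct_labelmap"), inherits(marker, "ct_marker"))
  cells <- cell_pixel_sets(labelmap)
  cal <- marker$calibration
  rows <- purrr::map2(cells, seq_along(cells), function(idx, i) {
    sf <- shape_features(idx, dim(labelmap$labels), labelmap$contours[[i]],
                         cal, labelmap$offset)
    inf <- intensity_features(marker$pixels[idx], sf$area)
    dplyr::bind_cols(
      tibble::tibble(cell_id = i),
      dplyr::rename_with(sf, ~ paste0("M1.", .x)),
      dplyr::rename_with(inf, ~ paste0("M1.", .x)))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(cell_id = integer(0))
  }
  tbl$relevant <- rep(TRUE, nrow(tbl))
  tbl$cell_type <- rep(NA_character_, nrow(tbl))
  tbl
}

#' Per-cell pixel sets of a label map
#'
#' @param labelmap A `ct_labelmap`.
#' @return List of integer vectors of linear indices, one per cell ID.
#' @export
cell_pixel_sets <- function(labelmap) {
  lab <- labelmap$labels
  idx <- which(lab > 0)
  split(idx, lab[idx])
}

#' Descriptive summary of a feature table
#'
#' Computes mean, median, sample variance, standard deviation, min, max,
#' quartiles (type-7 linear interpolation) and IQR for every numeric feature
#' column.
#'
#' @param table A feature table (tibble with `M*.` columns).
#' @return A tibble with one row per feature.
#' @export
summarize_features <- function(table) {
  if (nrow(table) < 1) stop("cannot summarize an empty feature table")
  num <- table |>
    dplyr::select(dplyr::where(is.numeric), -dplyr::any_of("cell_id"))
  purrr::imap(num, function(v, nm) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(feature = nm, mean = mean(v), median = stats::median(v),
                   variance = stats::var(v),
                   std = stats::sd(v), min = min(v), max = max(v),
                   Q1 = q[1], Q2 = q[2], Q3 = q[3], IQR = q[3] - q[1])
  }) |> dplyr::bind_rows()
}
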