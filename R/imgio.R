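#' Spatial calibration of an image plane
#'
#' A calibration converts pixel measurements to physical units. When
#' `calibrated` is `FALSE` the calibration is the identity (1 pixel by
#' 1 pixel, unit `"pixel"`).
#'
#' @param pixel_width Physical width of one pixel (> 0), e.g. in micrometres.
#' @param pixel_height Physical height of one pixel (> 0).
#' @param unit Name of the physical unit, e.g. `"um"`.
#' @return An object of class `ct_calibration` with fields `pixel_width`,
#'   `pixel_height`, `unit` and `calibrated`.
#' @examples
#' calibration(0.65, 0.65, "um")
#' calibration()          # uncalibrated: measurements stay in pixels
#' @export
calibration <- function(pixel_width = 1, pixel_height = 1, unit = "pixel") {
  stopifnot(is.numeric(pixel_width), length(pixel_width) == 1, pixel_width > 0,
            is.numeric(pixel_height), length(pixel_height) == 1, pixel_height > 0,
            is.character(unit), length(unit) == 1)
  calibrated <- !(pixel_width == 1 && pixel_height == 1 && unit == "pixel")
  structure(
    list(pixel_width = as.numeric(pixel_width),
         pixel_height = as.numeric(pixel_height),
         unit = unit, calibrated = calibrated),
    class = "ct_calibration"
  )
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g x %g %s/px%s\n", x$pixel_width, x$pixel_height,
              x$unit, if (x$calibrated) "" else " (uncalibrated)"))
  invisible(x)
}

marker_roles <- c("MarkerI", "MarkerII", "MarkerIII")

#' Construct a marker image
#'
#' Binds one 2D intensity plane to a marker role. Marker I is the channel
#' that defines what a cell is (typically a nuclear stain such as DAPI);
#' Markers II and III are measured inside each detected cell and drive the
#' cell-type classification.
#'
#' @param pixels Numeric or integer matrix (rows = image rows, columns =
#'   image columns) of nonnegative intensities.
#' @param role One of `"MarkerI"`, `"MarkerII"`, `"MarkerIII"`.
#' @param bit_depth Source bit depth, 8 or 16.
#' @param calibration A [calibration()] object.
#' @return An object of class `ct_marker`.
#' @export
marker_image <- function(pixels, role, bit_depth = 8, calibration = celltyper::calibration()) {
  if (!is.matrix(pixels)) stop("pixels must be a 2D matrix (single plane)")
  if (any(pixels < 0)) stop("pixel intensities must be nonnegative")
  role <- match.arg(role, marker_roles)
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  stopifnot(inherits(calibration, "ct_calibration"))
  structure(
    list(pixels = pixels, role = role, bit_depth = as.integer(bit_depth),
         calibration = calibration),
    class = "ct_marker"
  )
}

#' @export
print.ct_marker <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px, %d-bit, range [%g, %g]\n", x$role,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

max_intensity <- function(bit_depth) if (bit_depth == 16) 65535 else 255

#' Load a 2D single-plane image as raw channel planes
#'
#' Reads a TIFF (8- or 16-bit, 1 or 3 channels) or PNG (8-bit) file and
#' returns one intensity matrix per channel, in channel order (R, G, B for
#' RGB images). Pixel values are preserved losslessly at the native scale.
#' Multi-slice TIFFs (z-stacks, time series) and images with more than three
#' channels are rejected: the pipeline is restricted to 2D single-plane
#' material.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A list with `planes` (list of integer matrices), `bit_depth`
#'   (8 or 16) and `path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE, all = TRUE)
    if (length(img) != 1)
      stop("2D single-plane required: '", basename(path), "' has ",
           length(img), " slices (z-stacks/time series are not supported)")
    img <- img[[1]]
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth: ", bits)
    # readTIFF normalizes to [0,1] by value/(2^bits - 1): undo losslessly
    img <- round(img * max_intensity(bits))
  } else if (ext == "png") {
    img <- png::readPNG(path)
    img <- round(img * 255)  # readPNG normalizes to [0,1]; PNG support is 8-bit
    bits <- 8L
  } else {
    stop("unsupported format '", ext, "': only TIFF and PNG are accepted")
  }
  if (length(dim(img)) == 2) {
    planes <- list(matrix(as.integer(img), nrow(img), ncol(img)))
  } else if (length(dim(img)) == 3) {
    if (dim(img)[3] > 3)
      stop("at most 3 channels supported; '", basename(path), "' has ",
           dim(img)[3])
    planes <- lapply(seq_len(dim(img)[3]), function(k)
      matrix(as.integer(img[, , k]), dim(img)[1], dim(img)[2]))
  } else {
    stop("2D single-plane required")
  }
  list(planes = planes, bit_depth = as.integer(bits), path = path)
}

#' Write one intensity plane to a grayscale TIFF
#'
#' Inverse of [load_image()] for a single plane: values are written at the
#' native bit depth so that reloading yields an identical pixel array.
#'
#' @param pixels Integer matrix of intensities.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @export
write_plane <- function(pixels, path, bit_depth = 8) {
  stopifnot(is.matrix(pixels), bit_depth %in% c(8, 16))
  tiff::writeTIFF(pixels / max_intensity(bit_depth), path,
                  bits.per.sample = bit_depth)
  invisible(path)
}

#' Assign marker roles to loaded channel planes
#'
#' @param loaded Result of [load_image()].
#' @param mapping Named list or vector mapping marker role to 0-based channel
#'   index, e.g. `list(MarkerI = 0, MarkerII = 1)`. Marker I is mandatory and
#'   each role may appear at most once; unmapped planes are discarded.
#' @param calibration A [calibration()] applied to every marker.
#' @return Named list of [marker_image()] objects (by role).
#' @examples
#' \dontrun{
#' load_image("scene.tif") |>
#'   match_channels(list(MarkerI = 0, MarkerII = 1, MarkerIII = 2))
#' }
#' @export
match_channels <- function(loaded, mapping, calibration = celltyper::calibration()) {
  mapping <- as.list(mapping)
  roles <- names(mapping)
  if (is.null(roles) || !all(roles %in% marker_roles))
    stop("mapping names must be among: ", paste(marker_roles, collapse = ", "))
  if (anyDuplicated(roles)) stop("duplicate marker role in mapping")
  idx <- unlist(mapping)
  if (anyDuplicated(idx)) stop("duplicate channel index in mapping")
  if (!"MarkerI" %in% roles) stop("MarkerI must be assigned to exactly one channel")
  if (any(idx < 0 | idx >= length(loaded$planes)))
    stop("channel index out of range (image has ", length(loaded$planes),
         " channel(s), indices are 0-based)")
  out <- lapply(roles, function(r)
    marker_image(loaded$planes[[mapping[[r]] + 1L]], role = r,
                 bit_depth = loaded$bit_depth, calibration = calibration))
  stats::setNames(out, roles)
}

#' Define a region of interest
#'
#' Rasterizes a closed shape into a boolean mask congruent with the image.
#' Coordinates follow the package convention: x = column, y = row, 0-based,
#' origin at the top-left corner. A pixel belongs to the ROI if its centre
#' lies inside the shape (inclusive boundaries for the rectangle).
#'
#' @param shape `"rectangle"`, `"ellipse"`, `"polygon"` or `"none"`.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @param x,y For rectangle/ellipse: top-left corner (rectangle) or centre
#'   (ellipse), 0-based.
#' @param width,height Rectangle extent or ellipse full axes, in pixels.
#' @param xs,ys Polygon vertex coordinates (0-based), implicitly closed.
#' @return An object of class `ct_roi` with `mask` (logical matrix), `offset`
#'   (`c(x0, y0)` of the bounding box, 0-based) and `closed = TRUE`.
#' @export
roi_shape <- function(shape, dim, x = 0, y = 0, width = NULL, height = NULL,
                      xs = NULL, ys = NULL) {
  shape <- match.arg(shape, c("rectangle", "ellipse", "polygon", "none"))
  nr <- dim[1]; nc <- dim[2]
  # pixel-centre coordinates, 0-based
  cx <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  cy <- matrix(rep(0:(nr - 1), nc), nr, nc)
  mask <- switch(shape,
    none = matrix(TRUE, nr, nc),
    rectangle = {
      stopifnot(!is.null(width), !is.null(height))
      cx >= x & cx < x + width & cy >= y & cy < y + height
    },
    ellipse = {
      stopifnot(!is.null(width), !is.null(height))
      a <- width / 2; b <- height / 2
      ((cx - x) / a)^2 + ((cy - y) / b)^2 <= 1
    },
    polygon = {
      stopifnot(!is.null(xs), !is.null(ys), length(xs) == length(ys),
                length(xs) >= 3)
      point_in_polygon(as.vector(cx), as.vector(cy), xs, ys) |>
        matrix(nr, nc)
    })
  new_roi(mask)
}

new_roi <- function(mask) {
  if (!any(mask)) stop("ROI has no interior pixels (degenerate/open region)")
  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  structure(list(mask = mask,
                 offset = c(x0 = cols[1] - 1L, y0 = rows[1] - 1L),
                 closed = TRUE),
            class = "ct_roi")
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Restrict markers to a region of interest
#'
#' Crops every marker plane to the ROI bounding box and blanks pixels outside
#' the mask so they are excluded from all downstream analysis. The recorded
#' offset lets all reported cell coordinates be expressed in original-image
#' coordinates (cropped coordinate + offset).
#'
#' @param markers Named list of [marker_image()] objects.
#' @param roi A `ct_roi` from [roi_shape()], congruent with the image.
#' @return List with `markers` (cropped), `roi_mask` (cropped logical mask)
#'   and `offset` (`c(x0, y0)`).
#' @export
crop_to_roi <- function(markers, roi) {
  stopifnot(inherits(roi, "ct_roi"))
  if (!isTRUE(roi$closed)) stop("ROI must be a closed shape")
  d <- dim(markers[[1]]$pixels)
  if (!identical(dim(roi$mask), d))
    stop("ROI mask dimensions ", paste(dim(roi$mask), collapse = "x"),
         " do not match image ", paste(d, collapse = "x"))
  rows <- which(rowSums(roi$mask) > 0); cols <- which(colSums(roi$mask) > 0)
  rr <- rows[1]:rows[length(rows)]; cc <- cols[1]:cols[length(cols)]
  sub_mask <- roi$mask[rr, cc, drop = FALSE]
  cropped <- lapply(markers, function(m) {
    px <- m$pixels[rr, cc, drop = FALSE]
    px[!sub_mask] <- 0L
    marker_image(px, m$role, m$bit_depth, m$calibration)
  })
  list(markers = cropped, roi_mask = sub_mask,
       offset = c(x0 = cols[1] - 1L, y0 = rows[1] - 1L))
}

#' 256-bin intensity histogram of a marker plane
#'
#' Bin counts always sum to the pixel count. 16-bit planes are linearly
#' rescaled to the 0-255 bin range (value * 255 / 65535, rounded half up) so
#' that the classical 8-bit auto-threshold algorithms apply; the chosen
#' threshold is mapped back to the native scale by [binarize()].
#'
#' @param marker A [marker_image()] (or a plain intensity matrix).
#' @param bit_depth Used when `marker` is a bare matrix.
#' @return Integer vector of 256 counts for bins 0..255.
#' @export
channel_histogram <- function(marker, bit_depth = NULL) {
  if (inherits(marker, "ct_marker")) {
    px <- marker$pixels; bit_depth <- marker$bit_depth
  } else {
    px <- marker
    if (is.null(bit_depth)) bit_depth <- if (max(px) > 255) 16L else 8L
  }
  if (length(px) == 0) stop("empty image")
  b <- bin_index(px, bit_depth)
  tabulate(b + 1L, nbins = 256L)
}

# map native intensities to 0..255 bin indices (round half up for 16-bit)
bin_index <- function(px, bit_depth) {
  if (bit_depth == 16) as.integer(floor(px * 255 / 65535 + 0.5)) else as.integer(px)
}

# map a 0..255 bin threshold back to the native intensity scale
threshold_to_native <- function(t, bit_depth) {
  if (bit_depth == 16) t * 65535 / 255 else t
}
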