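#' Preprocessing steps
#'
#' An ordered, declarative chain of image-conditioning operations applied to
#' the Marker I plane before segmentation only: intensity features are always
#' measured on the raw, unpreprocessed planes so that measured statistics stay
#' comparable across runs.
#'
#' Available operations and parameters:
#' \describe{
#'   \item{gaussian_blur}{`sigma` (> 0, pixels) — Gaussian smoothing.}
#'   \item{median_filter}{`radius` (>= 1, pixels) — rank filter over a disk.}
#'   \item{mean_filter}{`radius` (>= 1, pixels) — box mean over a
#'     (2r+1)x(2r+1) window.}
#'   \item{subtract_background}{`radius` (> 0, pixels) — rolling-ball
#'     background estimation (grayscale opening with a ball-shaped,
#'     non-flat structuring element) subtracted from the image.}
#'   \item{enhance_contrast}{`saturation` (fraction in [0, 0.5)) — linear
#'     stretch clipping the given fraction of pixels at each tail.}
#'   \item{invert}{no parameters — `max_range - value`.}
#'   \item{gamma_correction}{`gamma` (> 0) — power law on normalized
#'     intensities.}
#' }
#' Convolution boundaries use reflection; every step preserves shape and bit
#' depth, and outputs are rounded back to the native integer range.
#'
#' @param op Operation name (see Details).
#' @param ... Numeric parameters of the operation.
#' @return A `ct_step` list with `op` and `params`.
#' @examples
#' preprocess_step("gaussian_blur", sigma = 2)
#' preprocess_step("invert")
#' @export
preprocess_step <- function(op, ...) {
  ops <- c("gaussian_blur", "median_filter", "mean_filter",
           "subtract_background", "enhance_contrast", "invert",
           "gamma_correction")
  if (!op %in% ops)
    stop("unknown preprocessing op '", op, "'; valid ops: ",
         paste(ops, collapse = ", "))
  params <- list(...)
  structure(list(op = op, params = params), class = "ct_step")
}

step_param <- function(step, name, default = NULL) {
  v <- step$params[[name]]
  if (is.null(v)) {
    if (is.null(default)) stop("step '", step$op, "' requires parameter '", name, "'")
    v <- default
  }
  as.numeric(v)
}

#' Apply a preprocessing chain to a marker image
#'
#' @param image A [marker_image()].
#' @param steps List of [preprocess_step()] objects, applied in order. An
#'   empty chain returns the input unchanged.
#' @return A [marker_image()] of identical shape and bit depth.
#' @export
apply_chain <- function(image, steps = list()) {
  stopifnot(inherits(image, "ct_marker"))
  px <- image$pixels
  maxv <- max_intensity(image$bit_depth)
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    if (!inherits(step, "ct_step")) stop("step ", i, " is not a preprocess_step")
    px <- tryCatch(
      apply_step(px, step, maxv),
      error = function(e) stop("preprocess step ", i, " (", step$op, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  marker_image(px, image$role, image$bit_depth, image$calibration)
}

apply_step <- function(px, step, maxv) {
  out <- switch(step$op,
    gaussian_blur = {
      sigma <- step_param(step, "sigma")
      if (sigma <= 0) stop("sigma must be > 0")
      ebi_filter(px, function(m) EBImage::gblur(m, sigma = sigma,
                                                boundary = "replicate"))
    },
    median_filter = {
      r <- step_param(step, "radius")
      if (r < 1) stop("radius must be >= 1")
      # EBImage::medianFilter wants [0,1] doubles
      ebi_filter(px / maxv, function(m) EBImage::medianFilter(m, size = round(r))) * maxv
    },
    mean_filter = {
      r <- round(step_param(step, "radius"))
      if (r < 1) stop("radius must be >= 1")
      k <- matrix(1, 2 * r + 1, 2 * r + 1); k <- k / sum(k)
      ebi_filter(px, function(m) EBImage::filter2(m, k, boundary = "replicate"))
    },
    subtract_background = {
      r <- step_param(step, "radius")
      if (r <= 0) stop("radius must be > 0")
      px - rolling_ball_background(px, r)
    },
    enhance_contrast = {
      s <- step_param(step, "saturation", 0.0035)
      if (s < 0 || s >= 0.5) stop("saturation must be in [0, 0.5)")
      q <- stats::quantile(px, c(s, 1 - s), names = FALSE, type = 7)
      if (q[2] <= q[1]) px else (px - q[1]) / (q[2] - q[1]) * maxv
    },
    invert = maxv - px,
    gamma_correction = {
      g <- step_param(step, "gamma")
      if (g <= 0) stop("gamma must be > 0")
      (px / maxv)^g * maxv
    })
  matrix(pmin(pmax(as.integer(floor(out + 0.5)), 0L), as.integer(maxv)),
         nrow(px), ncol(px))
}

# run an EBImage filter on a [row, col] matrix (EBImage is [x, y] = transposed)
ebi_filter <- function(px, f) {
  t(f(t(px)))
}

#' Rolling-ball background estimation
#'
#' Grayscale opening with a ball-shaped (spherical cap) structuring element:
#' erosion followed by dilation with the ball height profile, the classical
#' rolling-ball background. Exposed for inspection; [preprocess_step()]
#' `subtract_background` subtracts this from the image.
#'
#' @param px Intensity matrix.
#' @param radius Ball radius in pixels.
#' @return Background matrix of the same shape.
#' @export
rolling_ball_background <- function(px, radius) {
  r <- max(1, round(radius))
  dx <- rep(-r:r, times = 2 * r + 1)
  dy <- rep(-r:r, each = 2 * r + 1)
  keep <- dx^2 + dy^2 <= r^2
  dx <- dx[keep]; dy <- dy[keep]
  hgt <- sqrt(r^2 - dx^2 - dy^2)  # ball height above its rim plane
  eroded <- shift_reduce(px, dx, dy, -hgt, pmin, init = Inf)
  shift_reduce(eroded, dx, dy, +hgt, pmax, init = -Inf)
}

# grey morphology by accumulating shifted copies (replicate-padded)
shift_reduce <- function(px, dx, dy, off, reduce, init) {
  nr <- nrow(px); nc <- ncol(px)
  acc <- matrix(init, nr, nc)
  for (k in seq_along(dx)) {
    rows <- pmin(pmax(seq_len(nr) + dy[k], 1L), nr)
    cols <- pmin(pmax(seq_len(nc) + dx[k], 1L), nc)
    acc <- reduce(acc, px[rows, cols, drop = FALSE] + off[k])
  }
  acc
}
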