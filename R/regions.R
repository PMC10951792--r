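#' Region resize specification
#'
#' Measurements on Markers II/III can be taken in the region detected on
#' Marker I (`none`), a smaller region (`erode`) or a larger one (`dilate`),
#' using a disk structuring element of the given radius.
#'
#' @param mode `"none"`, `"erode"` or `"dilate"`.
#' @param radius Integer radius in pixels (>= 1; ignored for `none`).
#' @return A `ct_resize` list.
#' @export
resize_spec <- function(mode = c("none", "erode", "dilate"), radius = 1) {
  mode <- match.arg(mode)
  radius <- as.integer(radius)
  if (mode != "none" && radius < 1) stop("resize radius must be >= 1")
  structure(list(mode = mode, radius = radius), class = "ct_resize")
}

#' Resize every cell region of a label map
#'
#' Erosion and dilation act per cell with a disk of the given radius.
#' `erode(r)` is always a subset of the original pixels and `dilate(r)` a
#' superset; dilation never crosses into a neighbouring cell's original
#' pixels, and pixels contested by several dilated cells are assigned to the
#' cell whose original region is nearest (ties to the lower cell ID). A cell
#' fully erased by erosion yields an empty pixel set (flagged by downstream
#' measurement as missing values).
#'
#' @param labelmap A `ct_labelmap`.
#' @param spec A [resize_spec()].
#' @return Named list (by cell ID) of linear-index pixel sets.
#' @export
resize_regions <- function(labelmap, spec = resize_spec("none")) {
  stopifnot(inherits(labelmap, "ct_labelmap"), inherits(spec, "ct_resize"))
  cells <- cell_pixel_sets(labelmap)
  if (spec$mode == "none" || length(cells) == 0) return(cells)
  lab <- labelmap$labels
  nr <- nrow(lab); nc <- ncol(lab)
  r <- spec$radius
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  morph_one <- function(idx, op) {
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(rows) - r - 1L); r1 <- min(nr, max(rows) + r + 1L)
    c0 <- max(1L, min(cols) - r - 1L); c1 <- min(nc, max(cols) + r + 1L)
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
    out <- t(op(t(sub), brush))
    loc <- which(out > 0)
    lr <- (loc - 1L) %% nrow(sub) + 1L + r0 - 1L
    lc <- (loc - 1L) %/% nrow(sub) + 1L + c0 - 1L
    as.integer((lc - 1L) * nr + lr)
  }
  if (spec$mode == "erode") {
    return(lapply(cells, morph_one, op = EBImage::erode))
  }
  # dilate: resolve collisions against original labels and other dilations
  dil <- lapply(cells, morph_one, op = EBImage::dilate)
  ids <- as.integer(names(cells))
  extras <- purrr::map2(dil, seq_along(dil), function(d, i) {
    d <- setdiff(d, cells[[i]])
    d[lab[d] == 0L]                    # never cross into another cell's own pixels
  })
  claim <- tibble::tibble(
    px = unlist(extras, use.names = FALSE),
    cell = rep(ids, lengths(extras)))
  contested_px <- unique(claim$px[duplicated(claim$px)])
  if (length(contested_px) > 0) {
    keep <- claim |>
      dplyr::filter(.data$px %in% contested_px) |>
      dplyr::group_by(.data$px) |>
      dplyr::group_map(function(g, key) {
        p <- key$px
        pxr <- (p - 1L) %% nr + 1L; pxc <- (p - 1L) %/% nr + 1L
        d <- vapply(g$cell, function(cid) {
          o <- cells[[as.character(cid)]]
          orr <- (o - 1L) %% nr + 1L; occ <- (o - 1L) %/% nr + 1L
          min((orr - pxr)^2 + (occ - pxc)^2)
        }, numeric(1))
        # nearest original cell; ties to the lower cell id
        tibble::tibble(px = p, cell = g$cell[order(d, g$cell)][1])
      }) |> dplyr::bind_rows()
    claim <- claim |>
      dplyr::filter(!.data$px %in% contested_px) |>
      dplyr::bind_rows(keep)
  }
  out <- lapply(seq_along(ids), function(i) {
    sort(c(cells[[i]], claim$px[claim$cell == ids[i]]))
  })
  stats::setNames(out, names(cells))
}

#' Count bright foci in a cell region by intensity prominence
#'
#' Detects local maxima of the marker plane inside one cell. A maximum is
#' kept only if (a) it cannot be reached from any higher point without
#' descending by at least `tolerance` intensity levels (a flood-fill
#' prominence test in the spirit of the classical find-maxima analysis), and
#' (b) it rises at least `tolerance` above the cell region's median
#' intensity — the "local threshold" role of the tolerance parameter, which
#' keeps a spot-free nucleus at zero counts instead of reporting its global
#' intensity maximum. The default tolerance is 30. Plateaus of equal value
#' contribute a single maximum at their centroid, and equal-valued peaks
#' connected above `value - tolerance` are merged into the first in raster
#' order. Maxima whose position falls outside the (possibly resized) cell
#' region are discarded; a flat region has no maxima.
#'
#' @param marker A [marker_image()] (the raw plane; foci are searched
#'   unsmoothed unless `presmooth_sigma` is set).
#' @param cell_idx Linear pixel indices of the cell region.
#' @param tolerance Minimum intensity drop separating distinct foci (>= 0).
#' @param presmooth_sigma Optional Gaussian sigma applied to the search
#'   window before detection (default off).
#' @param offset ROI offset added to reported coordinates.
#' @return A list with `count`, `maxima` (tibble of x, y in original
#'   coordinates) and `tolerance`.
#' @export
find_foci <- function(marker, cell_idx, tolerance = 30, presmooth_sigma = NULL,
                      offset = c(x0 = 0, y0 = 0)) {
  stopifnot(inherits(marker, "ct_marker"), tolerance >= 0)
  if (length(cell_idx) == 0) stop("empty cell region")
  px <- marker$pixels
  nr <- nrow(px)
  rows <- (cell_idx - 1L) %% nr + 1L
  cols <- (cell_idx - 1L) %/% nr + 1L
  pad <- 2L
  r0 <- max(1L, min(rows) - pad); r1 <- min(nrow(px), max(rows) + pad)
  c0 <- max(1L, min(cols) - pad); c1 <- min(ncol(px), max(cols) + pad)
  w <- px[r0:r1, c0:c1, drop = FALSE]
  if (!is.null(presmooth_sigma) && presmooth_sigma > 0)
    w <- ebi_filter(w, function(m) EBImage::gblur(m, presmooth_sigma,
                                                  boundary = "replicate"))
  in_cell <- matrix(FALSE, nrow(w), ncol(w))
  in_cell[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  peaks <- prominence_maxima(w, tolerance)
  if (nrow(peaks) > 0) {
    keep <- in_cell[cbind(pmin(pmax(round(peaks$y) + 1, 1), nrow(w)),
                          pmin(pmax(round(peaks$x) + 1, 1), ncol(w)))]
    # local-threshold condition: peaks must stand out from the cell surface
    keep <- keep & (peaks$value >= stats::median(px[cell_idx]) + tolerance)
    peaks <- peaks[keep, , drop = FALSE]
  }
  maxima <- tibble::tibble(
    x = peaks$x + (c0 - 1L) + offset[[1]],
    y = peaks$y + (r0 - 1L) + offset[[2]],
    value = peaks$value)
  list(count = nrow(maxima), maxima = maxima, tolerance = tolerance)
}

# All prominence-accepted maxima of a window; returns 0-based x/y centroids.
prominence_maxima <- function(w, tolerance) {
  nr <- nrow(w); nc <- ncol(w)
  n <- nr * nc
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), value = numeric(0))
  if (n == 1) return(empty)
  # neighbour offsets (8-connectivity) as index shifts with border masks
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  row_of <- function(i) (i - 1L) %% nr + 1L
  col_of <- function(i) (i - 1L) %/% nr + 1L
  neighbors <- function(i) {
    r <- row_of(i); c <- col_of(i)
    out <- integer(0)
    for (k in seq_len(nrow(shifts))) {
      rr <- r + shifts$dy[k]; cc <- c + shifts$dx[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
    }
    out
  }
  # plateau components of equal value with no strictly higher 8-neighbour
  has_higher <- matrix(FALSE, nr, nc)
  has_lower <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(shifts))) {
    rsrc <- seq_len(nr) + shifts$dy[k]; csrc <- seq_len(nc) + shifts$dx[k]
    vr <- rsrc >= 1 & rsrc <= nr; vc <- csrc >= 1 & csrc <= nc
    nb <- matrix(-Inf, nr, nc)
    nb[vr, vc] <- w[rsrc[vr], csrc[vc], drop = FALSE]
    has_higher <- has_higher | (nb > w)
    has_lower <- has_lower | (nb > -Inf & nb < w)
  }
  cand_idx <- which(!has_higher & has_lower)
  if (length(cand_idx) == 0) return(empty)
  # group candidate pixels into plateaus (8-connected, equal value)
  cmask <- matrix(FALSE, nr, nc); cmask[cand_idx] <- TRUE
  comp <- label_components8(cmask, cand_idx)
  # split groups whose pixels differ in value (adjacent distinct maxima)
  comp <- as.integer(factor(paste(comp, w[cand_idx])))
  plats <- split(cand_idx, comp)
  vals <- vapply(plats, function(ii) w[ii[1]], numeric(1))
  firsts <- vapply(plats, function(ii) {
    min((row_of(ii) - 1L) * nc + (col_of(ii) - 1L))
  }, numeric(1))
  ord <- order(-vals, firsts)
  accepted_plateau <- matrix(FALSE, nr, nc)
  res_x <- numeric(0); res_y <- numeric(0); res_v <- numeric(0)
  for (pi in ord) {
    ii <- plats[[pi]]; v <- vals[pi]
    floor_v <- v - tolerance
    visited <- matrix(FALSE, nr, nc)
    visited[ii] <- TRUE
    frontier <- ii
    suppressed <- FALSE
    while (length(frontier) > 0) {
      nb <- unique(neighbors(frontier))
      nb <- nb[!visited[nb]]
      nb <- nb[w[nb] > floor_v]
      if (length(nb) == 0) break
      if (any(w[nb] > v) ||
          any(accepted_plateau[nb] & w[nb] == v)) { suppressed <- TRUE; break }
      visited[nb] <- TRUE
      frontier <- nb
    }
    if (!suppressed) {
      accepted_plateau[ii] <- TRUE
      res_x <- c(res_x, mean(col_of(ii)) - 1)
      res_y <- c(res_y, mean(row_of(ii)) - 1)
      res_v <- c(res_v, v)
    }
  }
  tibble::tibble(x = res_x, y = res_y, value = res_v)
}

#' Measure a secondary marker over (resized) cell regions
#'
#' Evaluates intensity features on the resized regions of Marker II or III;
#' shape features are not recomputed (geometry belongs to Marker I). When
#' foci counting is enabled a `foci_count` column is added. Cells whose
#' region became empty after erosion get missing values.
#'
#' @param labelmap A `ct_labelmap` from Marker I segmentation.
#' @param marker A [marker_image()] with role MarkerII or MarkerIII.
#' @param resize A [resize_spec()].
#' @param foci_enabled Count foci per cell?
#' @param tolerance Foci prominence tolerance.
#' @param presmooth_sigma Optional foci pre-smoothing sigma.
#' @return Tibble with `cell_id` and namespaced columns (`M2.*` / `M3.*`).
#' @export
measure_marker <- function(labelmap, marker, resize = resize_spec("none"),
                           foci_enabled = FALSE, tolerance = 30,
                           presmooth_sigma = NULL) {
  stopifnot(inherits(marker, "ct_marker"))
  if (marker$role == "MarkerI")
    stop("measure_marker is for Markers II/III; use marker1_features for Marker I")
  prefix <- role_prefix[[marker$role]]
  regions <- resize_regions(labelmap, resize)
  cal <- marker$calibration
  rows <- purrr::imap(regions, function(idx, id) {
    if (length(idx) == 0) {
      feat <- intensity_features(0, 0)   # template row, then blank it
      feat[1, ] <- NA_real_
    } else {
      feat <- intensity_features(marker$pixels[idx],
                                 length(idx) * cal$pixel_width * cal$pixel_height)
    }
    if (foci_enabled) {
      feat$foci_count <- if (length(idx) == 0) NA_integer_ else
        find_foci(marker, idx, tolerance, presmooth_sigma,
                  labelmap$offset)$count
    }
    dplyr::bind_cols(tibble::tibble(cell_id = as.integer(id)),
                     dplyr::rename_with(feat, ~ paste0(prefix, ".", .x)))
  })
  dplyr::bind_rows(rows)
}
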