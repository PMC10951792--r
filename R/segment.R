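#' Binarize a marker image at a threshold
#'
#' Foreground is strictly above the threshold when `dark_background = TRUE`
#' (bright objects), strictly below it otherwise. The threshold is given on
#' the native intensity scale of the image (see [channel_histogram()] for the
#' 16-bit to 8-bit bin mapping; use [threshold_to_native()] is internal —
#' [segment_marker()] composes the two).
#'
#' @param image A [marker_image()] or bare intensity matrix.
#' @param t Threshold on the native scale.
#' @param dark_background If `TRUE` (default) foreground is `pixel > t`.
#' @return A logical matrix (`TRUE` = foreground).
#' @export
binarize <- function(image, t, dark_background = TRUE) {
  px <- if (inherits(image, "ct_marker")) image$pixels else image
  if (dark_background) px > t else px < t
}

#' Fill interior holes of a binary mask
#'
#' Every background component not connected (4-connectivity, matching the
#' 8-connected foreground convention) to the image border becomes foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  m <- t(EBImage::fillHull(t(mask * 1L)))
  m > 0
}

#' Split touching objects with a binary watershed
#'
#' The classical distance-transform watershed on a binary mask: the Euclidean
#' distance map of the foreground is segmented from its local maxima (peaks
#' closer than 0.5 in distance height are merged), and the watershed lines
#' between basins are removed from the foreground as 1-pixel-wide separation
#' lines. The foreground pixel set is otherwise preserved, and the number of
#' connected components never decreases.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with separation lines cut to background.
#' @export
watershed_split <- function(mask) {
  if (!any(mask)) return(mask)
  dm <- EBImage::distmap(t(mask * 1L))
  lab <- t(EBImage::watershed(dm, tolerance = 0.5, ext = 1))
  if (max(lab) <= 1) return(mask)
  # cut 1-px lines: drop a pixel if an 8-neighbour carries a smaller positive label
  nr <- nrow(lab); nc <- ncol(lab)
  cut <- matrix(FALSE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    rows <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    cols <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    nb <- lab[rows, cols, drop = FALSE]
    cut <- cut | (lab > 0 & nb > 0 & nb < lab)
  }
  mask & !cut
}

#' Label connected cells and trace their contours
#'
#' Labels 8-connected foreground components (the standard particle-analysis
#' duality: 8-connected foreground, 4-connected background) with consecutive
#' IDs 1..N assigned in raster order of each component's first
#' (topmost-then-leftmost) pixel, and traces the outer crack-boundary polygon
#' of each label.
#'
#' @param mask Logical matrix.
#' @param offset `c(x0, y0)` added to all contour/centroid coordinates so
#'   results are reported in original-image coordinates after an ROI crop.
#' @return A list of class `ct_labelmap` with `labels` (integer matrix,
#'   0 = background), `n_cells`, `contours` (list of two-column matrices of
#'   polygon vertices, x = column, y = row, 0-based, in original-image
#'   coordinates) and `offset`.
#' @export
label_cells <- function(mask, offset = c(x0 = 0, y0 = 0)) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(structure(list(labels = labels, n_cells = 0L, contours = list(),
                          offset = offset), class = "ct_labelmap"))
  }
  comp <- label_components8(mask, idx)
  # order components by raster position (row-major) of their first pixel
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  raster_key <- (rows - 1L) * nc + (cols - 1L)
  first_key <- tapply(raster_key, comp, min)
  new_id <- integer(length(first_key))
  new_id[order(first_key)] <- seq_along(first_key)
  labels[idx] <- new_id[comp]
  n <- max(new_id)
  contours <- lapply(seq_len(n), function(i) trace_crack_boundary(labels == i, offset))
  structure(list(labels = labels, n_cells = as.integer(n), contours = contours,
                 offset = offset), class = "ct_labelmap")
}

#' @export
print.ct_labelmap <- function(x, ...) {
  cat(sprintf("<label map> %d x %d px, %d cell(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_cells))
  invisible(x)
}

# 8-connected components over foreground pixels via the pixel adjacency graph
label_components8 <- function(mask, idx = which(mask)) {
  nr <- nrow(mask)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  edges <- list()
  k <- 1
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + sh[1]; c2 <- cols + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(mask)
    j <- idx[ok] + sh[1] + sh[2] * nr
    keep <- mask[j]
    if (any(keep)) {
      edges[[k]] <- rbind(pos[idx[ok][keep]], pos[j[keep]])
      k <- k + 1
    }
  }
  if (length(edges) == 0) return(seq_along(idx))
  g <- igraph::graph_from_edgelist(t(do.call(cbind, edges)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(idx)]
}

# Trace the outer crack boundary (polygon over pixel corners) of a single
# region. Vertices are corner coordinates in the 0-based x/y convention, so
# the pixel at (x, y) occupies corners (x, y)..(x+1, y+1); the shoelace area
# of the polygon equals the pixel count for simply-connected regions.
trace_crack_boundary <- function(mask, offset = c(x0 = 0, y0 = 0)) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc & mask[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, nc), 1))]
  # directed crack edges with the region kept on a consistent side:
  #   top edge of pixel -> travel +x; bottom -> -x; left -> -y; right -> +y
  top <- !at(rows - 1L, cols)
  bot <- !at(rows + 1L, cols)
  lef <- !at(rows, cols - 1L)
  rig <- !at(rows, cols + 1L)
  x <- cols - 1L; y <- rows - 1L   # 0-based pixel coordinates
  segs <- cbind(
    if (any(top)) rbind(x[top], y[top], 1L, 0L),
    if (any(bot)) rbind(x[bot] + 1L, y[bot] + 1L, -1L, 0L),
    if (any(lef)) rbind(x[lef], y[lef] + 1L, 0L, -1L),
    if (any(rig)) rbind(x[rig] + 1L, y[rig], 0L, 1L))
  ns <- ncol(segs)
  # begin at the topmost-leftmost pixel's top-left corner heading +x
  start_px <- which.min((rows - 1L) * nc + cols)
  sx <- x[start_px]; sy <- y[start_px]
  cur <- which(segs[1, ] == sx & segs[2, ] == sy & segs[3, ] == 1L)[1]
  used <- logical(ns)
  verts_x <- integer(0); verts_y <- integer(0)
  for (step in seq_len(ns + 1L)) {
    used[cur] <- TRUE
    cx <- segs[1, cur]; cy <- segs[2, cur]
    dx <- segs[3, cur]; dy <- segs[4, cur]
    verts_x <- c(verts_x, cx); verts_y <- c(verts_y, cy)
    nx <- cx + dx; ny <- cy + dy
    if (nx == sx && ny == sy) break
    # outgoing edge at corner (nx, ny): prefer the turn away from the region,
    # then straight, then into it — keeps diagonally touching pixels
    # (8-connectivity) on a single outer loop
    turns <- list(c(dy, -dx), c(dx, dy), c(-dy, dx))
    cur <- NA_integer_
    for (tr in turns) {
      hit <- which(segs[1, ] == nx & segs[2, ] == ny &
                   segs[3, ] == tr[1] & segs[4, ] == tr[2] & !used)
      if (length(hit)) { cur <- hit[1]; break }
    }
    if (is.na(cur)) break
  }
  cbind(x = verts_x + offset[[1]], y = verts_y + offset[[2]])
}

#' Area enclosed by a polygon (shoelace formula)
#'
#' @param poly Two-column matrix of vertex coordinates.
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
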