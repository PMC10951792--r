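#' Run the full analysis on a single image
#'
#' Composes the pipeline stages in order, reading every setting from the
#' configuration: load and map channels, calibrate, crop to the ROI,
#' preprocess the Marker I plane, auto-threshold and binarize (optionally
#' fill holes and watershed-split), label cells, extract Marker I shape and
#' intensity features on the raw plane, flag relevant cells, measure Markers
#' II/III on resized regions (with optional foci counts), classify cell
#' types, and compute the configured reports. Deterministic for fixed inputs.
#'
#' @param image_path Path to a TIFF/PNG image.
#' @param config A validated [analysis_config()].
#' @param out_dir Optional output directory; when given, the per-image CSV
#'   outputs (`cells.csv`, `classification.csv`, `summary.csv`, and
#'   `quadrants.csv` / `fit.csv` / `scatter.csv` when configured) are
#'   written there, plus `labels.tif` when `save_labelmap` is set.
#' @return A `ct_result` list: `table` (the feature table), `summary`,
#'   `labelmap`, `threshold` (bin and native scale), `quadrants`, `fit`,
#'   `config`, `image`.
#' @export
run_single <- function(image_path, config, out_dir = NULL) {
  validate_config(config)
  res <- tryCatch(
    run_single_impl(image_path, config),
    error = function(e) stop("while processing '", basename(image_path), "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

run_single_impl <- function(image_path, config) {
  loaded <- load_image(image_path)
  markers <- match_channels(loaded, config$channels, config$calibration)
  offset <- c(x0 = 0, y0 = 0)
  roi_mask <- NULL
  if (!is.null(config$roi) && !identical(config$roi$type, "none")) {
    roi <- do.call(roi_shape, c(list(shape = config$roi$type,
                                     dim = dim(markers$MarkerI$pixels)),
                                config$roi[setdiff(names(config$roi), "type")]))
    cropped <- crop_to_roi(markers, roi)
    markers <- cropped$markers
    offset <- cropped$offset
    roi_mask <- cropped$roi_mask
  }
  m1 <- markers$MarkerI
  pre <- apply_chain(m1, config$preprocess)
  hist <- channel_histogram(pre)
  t_bin <- auto_threshold(hist, config$segment$method)
  t_native <- threshold_to_native(t_bin, pre$bit_depth)
  mask <- binarize(pre, t_native, config$segment$dark_background)
  if (!is.null(roi_mask)) mask <- mask & roi_mask
  if (isTRUE(config$segment$fill_holes)) mask <- fill_holes(mask)
  if (isTRUE(config$segment$watershed)) mask <- watershed_split(mask)
  labelmap <- label_cells(mask, offset)

  table <- marker1_features(labelmap, m1) |>
    apply_filters(config$filters)
  for (mk in c("MarkerII", "MarkerIII")) {
    if (!is.null(markers[[mk]])) {
      slot <- if (mk == "MarkerII") "markerII" else "markerIII"
      ms <- config[[slot]]
      cols <- measure_marker(labelmap, markers[[mk]], resize = ms$resize,
                             foci_enabled = isTRUE(ms$foci$enabled),
                             tolerance = ms$foci$tolerance,
                             presmooth_sigma = ms$foci$presmooth_sigma)
      table <- dplyr::left_join(table, cols, by = "cell_id")
    }
  }
  table <- classify_cells(table, config$cell_types)

  quadrants <- NULL
  if (!is.null(config$report$quadrants)) {
    q <- config$report$quadrants
    quadrants <- quadrant_counts(table, q$x, q$y, q$thr_x, q$thr_y)
  }
  fit <- NULL
  if (!is.null(config$report$fit) && !is.null(config$report$scatter)) {
    s <- config$report$scatter
    rel <- table[table$relevant, ]
    fit <- tryCatch(
      fit_curve(rel[[s$x]], rel[[s$y]], model = config$report$fit$model,
                degree = config$report$fit$degree %||% 2),
      error = function(e) { warning("curve fit skipped: ",
                                    conditionMessage(e)); NULL })
  }
  structure(list(
    table = table,
    summary = if (nrow(table)) summarize_features(table) else NULL,
    labelmap = labelmap,
    threshold = c(bin = t_bin, native = t_native),
    quadrants = quadrants, fit = fit,
    config = config, image = image_path), class = "ct_result")
}

#' @export
print.ct_result <- function(x, ...) {
  cat(sprintf("<celltyper result> %s: %d cell(s), %d relevant\n",
              basename(x$image), nrow(x$table), sum(x$table$relevant)))
  if (nrow(x$table)) {
    counts <- table(x$table$cell_type)
    cat("  cell types:",
        paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a pipeline result
#'
#' @param x A `ct_result` from [run_single()].
#' @param ... Unused.
#' @return The per-cell feature table (tibble).
#' @export
tidy.ct_result <- function(x, ...) x$table

#' One-row summary of a pipeline result
#'
#' @param x A `ct_result` from [run_single()].
#' @param ... Unused.
#' @return Tibble with image, cell counts and threshold used.
#' @export
glance.ct_result <- function(x, ...) {
  tibble::tibble(image = basename(x$image), n_cells = nrow(x$table),
                 n_relevant = sum(x$table$relevant),
                 threshold = x$threshold[["native"]],
                 method = x$config$segment$method)
}

# CSV at 6 significant digits, with the coordinate-convention header comment;
# formatting is fixed so repeated runs are byte-identical.
write_ct_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("# coordinates: x=column, y=row, 0-based, origin top-left",
             con, sep = "\n")
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      ifelse(is.na(col), "", sprintf("%.6g", col))
    } else if (is.character(col)) {
      ifelse(is.na(col), "",
             paste0("\"", gsub("\"", "\"\"", col), "\""))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  }
  out <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(df)))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  if (nrow(df) > 0)
    writeLines(apply(out, 1, paste, collapse = ","), con, sep = "\n")
  invisible(path)
}

#' Read a CSV written by the pipeline
#'
#' @param path CSV path.
#' @return A tibble (the coordinate-convention comment line is skipped).
#' @export
read_ct_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    check.names = FALSE))
}

write_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ct_csv(res$table, file.path(out_dir, "cells.csv"))
  write_ct_csv(res$table[, c("cell_id", "relevant", "cell_type",
                             "all_matching_types")],
               file.path(out_dir, "classification.csv"))
  if (!is.null(res$summary))
    write_ct_csv(res$summary, file.path(out_dir, "summary.csv"))
  if (!is.null(res$quadrants)) {
    q <- tibble::as_tibble(res$quadrants)
    q <- dplyr::bind_cols(tibble::tibble(
      feature_x = attr(res$quadrants, "feature_x"),
      feature_y = attr(res$quadrants, "feature_y"),
      thr_x = attr(res$quadrants, "thr_x"),
      thr_y = attr(res$quadrants, "thr_y")), q)
    write_ct_csv(q, file.path(out_dir, "quadrants.csv"))
  }
  if (!is.null(res$fit)) {
    f <- res$fit
    write_ct_csv(tibble::tibble(model = f$model, term = names(f$params),
                                estimate = f$params, r_squared = f$r_squared),
                 file.path(out_dir, "fit.csv"))
  }
  if (!is.null(res$config$report$scatter)) {
    s <- res$config$report$scatter
    colmap <- stats::setNames(
      vapply(res$config$cell_types, `[[`, character(1), "color"),
      vapply(res$config$cell_types, `[[`, character(1), "name"))
    rel <- res$table[res$table$relevant, ]
    write_ct_csv(tibble::tibble(
      cell_id = rel$cell_id, x = rel[[s$x]], y = rel[[s$y]],
      cell_type = rel$cell_type,
      color = unname(ifelse(rel$cell_type %in% names(colmap),
                            colmap[rel$cell_type], "#808080"))),
      file.path(out_dir, "scatter.csv"))
  }
  if (isTRUE(res$config$save_labelmap))
    tiff::writeTIFF(res$labelmap$labels / 65535,
                    file.path(out_dir, "labels.tif"), bits.per.sample = 16)
  invisible(out_dir)
}
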