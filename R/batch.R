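#' Run an analysis over a directory of images
#'
#' Applies the configured analysis to every supported image in `input_dir`
#' (lexicographic filename order), writing one output folder per image plus a
#' `summary` folder with the set-level summary table. Per-image results are
#' identical to [run_single()] on each file. A failure on one image is
#' logged, recorded in the summary, and does not stop the batch.
#'
#' @param input_dir Directory containing TIFF/PNG images.
#' @param output_dir Output directory (created if needed).
#' @param config A validated [analysis_config()].
#' @param verbose Log one line per image?
#' @return A `ct_batch` list: `summary` (tibble: image, status, n_cells,
#'   n_relevant, one count column per cell type plus `unknown` and
#'   `excluded`), and `results` (per-image `ct_result` objects, failures as
#'   `NULL`).
#' @export
run_batch <- function(input_dir, output_dir, config, verbose = TRUE) {
  validate_config(config)
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  files <- list.files(input_dir, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE)
  files <- files[order(files, method = "radix")]
  if (length(files) == 0)
    stop("no supported images (TIFF/PNG) in ", input_dir)
  ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)

  type_names <- c(vapply(config$cell_types, `[[`, character(1), "name"),
                  "unknown", "excluded")
  results <- vector("list", length(files))
  names(results) <- files
  rows <- lapply(seq_along(files), function(i) {
    f <- files[i]
    stem <- tools::file_path_sans_ext(f)
    res <- tryCatch(
      run_single(file.path(input_dir, f), config,
                 out_dir = file.path(output_dir, stem)),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message("[celltyper] FAILED ", f, ": ", conditionMessage(res))
      counts <- stats::setNames(rep(NA_integer_, length(type_names)), type_names)
      tibble::tibble(image = f, status = "failed",
                     message = conditionMessage(res),
                     n_cells = NA_integer_, n_relevant = NA_integer_,
                     !!!counts)
    } else {
      results[[f]] <<- res
      counts <- vapply(type_names, function(tn)
        sum(res$table$cell_type == tn), integer(1))
      if (verbose)
        message("[celltyper] ", f, ": ", nrow(res$table), " cells, ",
                sum(res$table$relevant), " relevant")
      tibble::tibble(image = f, status = "ok", message = "",
                     n_cells = nrow(res$table),
                     n_relevant = sum(res$table$relevant), !!!counts)
    }
  })
  summary <- dplyr::bind_rows(rows)
  dir.create(file.path(output_dir, "summary"), showWarnings = FALSE)
  write_ct_csv(summary, file.path(output_dir, "summary", "summary.csv"))
  structure(list(summary = summary, results = results), class = "ct_batch")
}

#' @export
print.ct_batch <- function(x, ...) {
  cat(sprintf("<celltyper batch> %d image(s), %d ok, %d failed\n",
              nrow(x$summary), sum(x$summary$status == "ok"),
              sum(x$summary$status == "failed")))
  invisible(x)
}
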