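CONFIG_SCHEMA_VERSION <- "1.0"

shape_feature_names <- c("area", "perimeter", "circularity", "roundness",
                         "aspect_ratio", "solidity", "feret_max", "feret_min",
                         "ellipse_major", "ellipse_minor", "ellipse_angle",
                         "centroid_x", "centroid_y", "bbox_x", "bbox_y",
                         "bbox_w", "bbox_h", "area_px")
intensity_feature_names <- c("mean", "median", "mode", "std", "min", "max",
                             "integrated_density", "raw_integrated_density",
                             "skewness", "kurtosis")

valid_feature_names <- function() {
  c(paste0("M1.", c(shape_feature_names, intensity_feature_names)),
    paste0("M2.", c(intensity_feature_names, "foci_count")),
    paste0("M3.", c(intensity_feature_names, "foci_count")))
}

#' Analysis configuration
#'
#' The complete, serializable description of every pipeline choice — channel
#' mapping, calibration, ROI, preprocessing chain, segmentation options,
#' region resize and foci settings per secondary marker, relevance filters,
#' cell-type definitions and report options — sufficient to rerun an analysis
#' in batch mode. Configurations round-trip losslessly through XML via
#' [save_config()] / [load_config()] and are validated before any image is
#' processed.
#'
#' @param channels Named list of 0-based channel indices; `MarkerI` is
#'   mandatory.
#' @param calibration A [calibration()].
#' @param roi `NULL`/`"none"` or a list with `type`
#'   (`rectangle`/`ellipse`/`polygon`) and its coordinates as in
#'   [roi_shape()].
#' @param preprocess List of [preprocess_step()] objects (Marker I only).
#' @param segment List: `method` (one of [threshold_methods()]), `watershed`,
#'   `fill_holes`, `dark_background` (logicals).
#' @param markerII,markerIII Lists: `resize` ([resize_spec()]) and `foci`
#'   (list with `enabled`, `tolerance`, optional `presmooth_sigma`).
#' @param filters List of [relevance_filter()] objects.
#' @param cell_types List of [cell_type()] definitions.
#' @param report List with optional `scatter` (`list(x, y)`), `quadrants`
#'   (`list(x, y, thr_x, thr_y)`), `fit` (`list(model, degree)`).
#' @param save_labelmap Write the labelled image as 16-bit TIFF debug output?
#' @return A validated `ct_config` object.
#' @export
analysis_config <- function(channels = list(MarkerI = 0),
                            calibration = celltyper::calibration(),
                            roi = NULL,
                            preprocess = list(),
                            segment = list(),
                            markerII = list(),
                            markerIII = list(),
                            filters = list(),
                            cell_types = list(),
                            report = list(),
                            save_labelmap = FALSE) {
  seg_defaults <- list(method = "Default", watershed = FALSE,
                       fill_holes = FALSE, dark_background = TRUE)
  segment <- utils::modifyList(seg_defaults, segment)
  mk_marker <- function(m) {
    r <- m$resize %||% resize_spec("none")
    if (!inherits(r, "ct_resize")) r <- do.call(resize_spec, r)
    f <- m$foci %||% list()
    # canonical shape so configs compare identical after an XML round-trip
    foci <- list(enabled = isTRUE(f$enabled), tolerance = f$tolerance %||% 30)
    foci["presmooth_sigma"] <- list(f$presmooth_sigma)
    list(resize = r, foci = foci)
  }
  cfg <- structure(list(
    schema_version = CONFIG_SCHEMA_VERSION,
    channels = channels, calibration = calibration, roi = roi,
    preprocess = preprocess, segment = segment,
    markerII = mk_marker(markerII), markerIII = mk_marker(markerIII),
    filters = filters, cell_types = cell_types, report = report,
    save_labelmap = isTRUE(save_labelmap)), class = "ct_config")
  validate_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' Checks channel mapping, method and feature names, and cross-field
#' consistency (e.g. a constraint on Marker III requires a Marker III
#' channel). Called by [analysis_config()], [save_config()] and
#' [load_config()].
#'
#' @param cfg A `ct_config`.
#' @return The config, invisibly; errors describe the offending field.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ct_config"))
  if (!identical(cfg$schema_version, CONFIG_SCHEMA_VERSION))
    stop("unsupported schema_version '", cfg$schema_version,
         "' (this package writes version ", CONFIG_SCHEMA_VERSION, ")")
  ch <- cfg$channels
  if (!"MarkerI" %in% names(ch)) stop("config: channels must map MarkerI")
  if (!all(names(ch) %in% marker_roles))
    stop("config: unknown channel role(s): ",
         paste(setdiff(names(ch), marker_roles), collapse = ", "))
  if (anyDuplicated(unlist(ch))) stop("config: duplicate channel index")
  normalize_method(cfg$segment$method)
  for (s in cfg$preprocess)
    if (!inherits(s, "ct_step")) stop("config: preprocess entries must be steps")
  mapped <- names(ch)
  prefix_ok <- c("M1", if ("MarkerII" %in% mapped) "M2",
                 if ("MarkerIII" %in% mapped) "M3")
  known <- valid_feature_names()
  check_feat <- function(f, where) {
    if (!f %in% known)
      stop("config: ", where, " references unknown feature '", f,
           "'; valid names: ", paste(known, collapse = ", "))
    pre <- sub("\\..*", "", f)
    if (!pre %in% prefix_ok)
      stop("config: ", where, " references ", f,
           " but no channel is mapped for that marker")
  }
  for (f in cfg$filters) check_feat(f$feature, "relevance filter")
  for (ty in cfg$cell_types) {
    for (cs in ty$constraints) {
      if (cs$form == "interval") check_feat(cs$feature, paste0("cell type '", ty$name, "'"))
      else { check_feat(cs$left, paste0("cell type '", ty$name, "'"))
             check_feat(cs$right, paste0("cell type '", ty$name, "'")) }
    }
  }
  nms <- vapply(cfg$cell_types, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("config: duplicate cell type name")
  for (fld in c("scatter", "quadrants")) {
    r <- cfg$report[[fld]]
    if (!is.null(r)) { check_feat(r$x, fld); check_feat(r$y, fld) }
  }
  if (!is.null(cfg$report$fit))
    match.arg(cfg$report$fit$model,
              c("linear", "polynomial", "power", "logarithmic", "exponential"))
  invisible(cfg)
}

num2chr <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "Inf" else "-Inf")
  sprintf("%.17g", x)
}

#' Save an analysis configuration as XML
#'
#' The XML is human-readable and hand-editable; [load_config()] restores a
#' structurally identical configuration.
#'
#' @param cfg A validated `ct_config`.
#' @param path Output file path.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  doc <- xml2::xml_new_root("celltyper_config",
                            schema_version = cfg$schema_version)
  ch <- xml2::xml_add_child(doc, "channels")
  for (r in names(cfg$channels))
    xml2::xml_set_attr(ch, sub("Marker", "marker", r),
                       as.character(cfg$channels[[r]]))
  cal <- cfg$calibration
  xml2::xml_add_child(doc, "calibration",
                      pixel_width = num2chr(cal$pixel_width),
                      pixel_height = num2chr(cal$pixel_height),
                      unit = cal$unit)
  roi <- cfg$roi
  if (is.null(roi) || identical(roi$type, "none")) {
    xml2::xml_add_child(doc, "roi", type = "none")
  } else {
    nd <- xml2::xml_add_child(doc, "roi", type = roi$type)
    for (p in setdiff(names(roi), "type"))
      xml2::xml_set_attr(nd, p, paste(vapply(roi[[p]], num2chr, character(1)),
                                      collapse = " "))
  }
  pp <- xml2::xml_add_child(doc, "preprocess")
  for (s in cfg$preprocess) {
    nd <- xml2::xml_add_child(pp, "step", op = s$op)
    for (p in names(s$params))
      xml2::xml_set_attr(nd, p, num2chr(s$params[[p]]))
  }
  xml2::xml_add_child(doc, "segment", method = cfg$segment$method,
                      watershed = tolower(cfg$segment$watershed),
                      fill_holes = tolower(cfg$segment$fill_holes),
                      dark_background = tolower(cfg$segment$dark_background))
  for (mk in c("markerII", "markerIII")) {
    m <- cfg[[mk]]
    nd <- xml2::xml_add_child(doc, mk)
    xml2::xml_add_child(nd, "resize", mode = m$resize$mode,
                        radius = as.character(m$resize$radius))
    fc <- xml2::xml_add_child(nd, "foci", enabled = tolower(m$foci$enabled),
                              tolerance = num2chr(m$foci$tolerance))
    if (!is.null(m$foci$presmooth_sigma))
      xml2::xml_set_attr(fc, "presmooth_sigma", num2chr(m$foci$presmooth_sigma))
  }
  fl <- xml2::xml_add_child(doc, "filters")
  for (f in cfg$filters)
    xml2::xml_add_child(fl, "filter", feature = f$feature,
                        min = num2chr(f$min), max = num2chr(f$max))
  cts <- xml2::xml_add_child(doc, "cell_types")
  for (ty in cfg$cell_types) {
    nd <- xml2::xml_add_child(cts, "cell_type", name = ty$name, color = ty$color)
    for (cs in ty$constraints) {
      if (cs$form == "interval") {
        b2c <- function(b) if (is.character(b)) b else num2chr(b)
        xml2::xml_add_child(nd, "constraint", feature = cs$feature,
                            min = b2c(cs$min), max = b2c(cs$max))
      } else {
        xml2::xml_add_child(nd, "constraint", left = cs$left,
                            relation = cs$relation, right = cs$right)
      }
    }
  }
  rp <- xml2::xml_add_child(doc, "report")
  if (!is.null(cfg$report$scatter))
    xml2::xml_add_child(rp, "scatter", x = cfg$report$scatter$x,
                        y = cfg$report$scatter$y)
  if (!is.null(cfg$report$quadrants))
    xml2::xml_add_child(rp, "quadrants", x = cfg$report$quadrants$x,
                        y = cfg$report$quadrants$y,
                        thr_x = num2chr(cfg$report$quadrants$thr_x),
                        thr_y = num2chr(cfg$report$quadrants$thr_y))
  if (!is.null(cfg$report$fit))
    xml2::xml_add_child(rp, "fit", model = cfg$report$fit$model,
                        degree = as.character(cfg$report$fit$degree %||% 2))
  if (cfg$save_labelmap)
    xml2::xml_add_child(doc, "debug", save_labelmap = "true")
  xml2::write_xml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chr2num <- function(s) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) && !s %in% c("NaN", "NA")) stop("expected a number, got '", s, "'")
  v
}
chr2bool <- function(s) {
  if (!s %in% c("true", "false")) stop("expected 'true' or 'false', got '", s, "'")
  s == "true"
}

#' Load an analysis configuration from XML
#'
#' Strict parser: unknown elements or attributes are rejected with their
#' location, the schema version is checked, and the restored configuration is
#' re-validated.
#'
#' @param path Path to a config XML written by [save_config()] (or edited by
#'   hand).
#' @return A validated `ct_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "celltyper_config")
    stop("config: root element must be <celltyper_config>, found <",
         xml2::xml_name(doc), ">")
  ver <- xml2::xml_attr(doc, "schema_version")
  if (is.na(ver) || !identical(ver, CONFIG_SCHEMA_VERSION))
    stop("config: schema_version '", ver, "' not supported (expected ",
         CONFIG_SCHEMA_VERSION, ")")
  known_children <- c("channels", "calibration", "roi", "preprocess",
                      "segment", "markerII", "markerIII", "filters",
                      "cell_types", "report", "debug")
  kids <- xml2::xml_children(doc)
  bad <- setdiff(xml2::xml_name(kids), known_children)
  if (length(bad))
    stop("config: unknown element(s) under <celltyper_config>: ",
         paste0("<", bad, ">", collapse = ", "))
  get1 <- function(nm) {
    nd <- xml2::xml_find_first(doc, nm)
    if (inherits(nd, "xml_missing")) stop("config: missing mandatory <", nm, ">")
    nd
  }
  attrs_of <- function(nd, allowed, where) {
    a <- xml2::xml_attrs(nd)
    bad <- setdiff(names(a), allowed)
    if (length(bad))
      stop("config: unknown attribute(s) ", paste(bad, collapse = ", "),
           " on <", where, ">")
    a
  }
  # channels
  a <- attrs_of(get1("channels"), c("markerI", "markerII", "markerIII"), "channels")
  channels <- stats::setNames(
    lapply(a, function(v) as.integer(chr2num(v))),
    sub("marker", "Marker", names(a)))
  # calibration
  a <- attrs_of(get1("calibration"), c("pixel_width", "pixel_height", "unit"),
                "calibration")
  cal <- calibration(chr2num(a[["pixel_width"]]), chr2num(a[["pixel_height"]]),
                     a[["unit"]])
  # roi
  rnode <- get1("roi")
  rtype <- xml2::xml_attr(rnode, "type")
  roi <- if (identical(rtype, "none")) NULL else {
    a <- xml2::xml_attrs(rnode)
    allowed <- c("type", "x", "y", "width", "height", "xs", "ys")
    bad <- setdiff(names(a), allowed)
    if (length(bad)) stop("config: unknown attribute(s) on <roi>: ",
                          paste(bad, collapse = ", "))
    out <- list(type = rtype)
    for (p in setdiff(names(a), "type"))
      out[[p]] <- vapply(strsplit(a[[p]], " ")[[1]], chr2num, numeric(1),
                         USE.NAMES = FALSE)
    out
  }
  # preprocess
  steps <- lapply(xml2::xml_children(get1("preprocess")), function(nd) {
    if (xml2::xml_name(nd) != "step")
      stop("config: only <step> allowed inside <preprocess>, found <",
           xml2::xml_name(nd), ">")
    a <- xml2::xml_attrs(nd)
    params <- lapply(a[setdiff(names(a), "op")], chr2num)
    do.call(preprocess_step, c(list(op = a[["op"]]), params))
  })
  # segment
  a <- attrs_of(get1("segment"),
                c("method", "watershed", "fill_holes", "dark_background"),
                "segment")
  segment <- list(method = a[["method"]],
                  watershed = chr2bool(a[["watershed"]]),
                  fill_holes = chr2bool(a[["fill_holes"]]),
                  dark_background = chr2bool(a[["dark_background"]]))
  # secondary markers
  read_marker <- function(nm) {
    nd <- get1(nm)
    rs <- xml2::xml_find_first(nd, "resize")
    fc <- xml2::xml_find_first(nd, "foci")
    a <- attrs_of(rs, c("mode", "radius"), paste0(nm, "/resize"))
    b <- attrs_of(fc, c("enabled", "tolerance", "presmooth_sigma"),
                  paste0(nm, "/foci"))
    list(resize = resize_spec(a[["mode"]], as.integer(chr2num(a[["radius"]]))),
         foci = list(enabled = chr2bool(b[["enabled"]]),
                     tolerance = chr2num(b[["tolerance"]]),
                     presmooth_sigma = if ("presmooth_sigma" %in% names(b))
                       chr2num(b[["presmooth_sigma"]]) else NULL))
  }
  # filters
  filters <- lapply(xml2::xml_children(get1("filters")), function(nd) {
    a <- attrs_of(nd, c("feature", "min", "max"), "filter")
    relevance_filter(a[["feature"]], chr2num(a[["min"]]), chr2num(a[["max"]]))
  })
  # cell types
  types <- lapply(xml2::xml_children(get1("cell_types")), function(nd) {
    a <- attrs_of(nd, c("name", "color"), "cell_type")
    cons <- lapply(xml2::xml_children(nd), function(cn) {
      ca <- xml2::xml_attrs(cn)
      if ("feature" %in% names(ca)) {
        parse_bound <- function(s) if (s %in% c("Q1", "Q2", "Q3")) s else chr2num(s)
        constraint(ca[["feature"]], parse_bound(ca[["min"]]),
                   parse_bound(ca[["max"]]))
      } else {
        constraint(left = ca[["left"]], relation = ca[["relation"]],
                   right = ca[["right"]])
      }
    })
    cell_type(a[["name"]], a[["color"]], cons)
  })
  # report
  rep_nd <- get1("report")
  report <- list()
  for (nd in xml2::xml_children(rep_nd)) {
    nm <- xml2::xml_name(nd)
    a <- xml2::xml_attrs(nd)
    report[[nm]] <- switch(nm,
      scatter = list(x = a[["x"]], y = a[["y"]]),
      quadrants = list(x = a[["x"]], y = a[["y"]],
                       thr_x = chr2num(a[["thr_x"]]),
                       thr_y = chr2num(a[["thr_y"]])),
      fit = list(model = a[["model"]], degree = as.integer(chr2num(a[["degree"]]))),
      stop("config: unknown element <", nm, "> inside <report>"))
  }
  dbg <- xml2::xml_find_first(doc, "debug")
  save_labelmap <- !inherits(dbg, "xml_missing") &&
    identical(xml2::xml_attr(dbg, "save_labelmap"), "true")
  analysis_config(channels = channels, calibration = cal, roi = roi,
                  preprocess = steps, segment = segment,
                  markerII = read_marker("markerII"),
                  markerIII = read_marker("markerIII"),
                  filters = filters, cell_types = types, report = report,
                  save_labelmap = save_labelmap)
}

#' @export
print.ct_config <- function(x, ...) {
  cat("<celltyper config> schema", x$schema_version, "\n")
  cat("  channels:", paste(names(x$channels), unlist(x$channels),
                           sep = "=", collapse = ", "), "\n")
  cat("  segment:", x$segment$method,
      if (x$segment$watershed) "+watershed",
      if (x$segment$fill_holes) "+fill_holes", "\n")
  cat("  filters:", length(x$filters), "| cell types:",
      length(x$cell_types), "\n")
  invisible(x)
}
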