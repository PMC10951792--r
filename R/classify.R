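#' Relevance filter
#'
#' An inclusive interval on a Marker I feature; cells must satisfy every
#' filter to be flagged relevant, and only relevant cells are classified.
#'
#' @param feature Namespaced Marker I feature name, e.g. `"M1.area"`.
#' @param min,max Inclusive bounds (default unbounded).
#' @return A `ct_filter` list.
#' @examples
#' relevance_filter("M1.area", min = 5)   # drop debris below 5 px^2
#' @export
relevance_filter <- function(feature, min = -Inf, max = Inf) {
  if (!startsWith(feature, "M1."))
    stop("relevance filters apply to Marker I features only (got '", feature, "')")
  if (min > max) stop("filter min must be <= max")
  structure(list(feature = feature, min = min, max = max), class = "ct_filter")
}

#' Cell-type constraint
#'
#' Either an inclusive interval on one feature (`feature`, `min`, `max`) or a
#' comparison between two feature columns (`left`, `relation`, `right`), e.g.
#' average Marker II intensity above average Marker I intensity. Interval
#' bounds may also be the strings `"Q1"`, `"Q2"` or `"Q3"`, which are
#' resolved per analysis as the type-7 quartiles of that feature over the
#' relevant cells (so batch runs recompute them per image): "in the Q4
#' quartile" is `min = "Q3"`, "in Q1" is `max = "Q1"`.
#'
#' @param feature,min,max Interval form.
#' @param left,relation,right Comparison form; relation one of
#'   `"<", "<=", ">", ">="`.
#' @return A `ct_constraint` list.
#' @examples
#' constraint("M2.foci_count", min = 8)
#' constraint(left = "M2.mean", relation = ">", right = "M1.mean")
#' constraint("M1.circularity", min = "Q3")   # circularity in the top quartile
#' @export
constraint <- function(feature = NULL, min = -Inf, max = Inf,
                       left = NULL, relation = NULL, right = NULL) {
  if (!is.null(feature)) {
    chk <- function(b) is.numeric(b) || (is.character(b) && b %in% c("Q1", "Q2", "Q3"))
    if (!chk(min) || !chk(max))
      stop("constraint bounds must be numeric or one of 'Q1','Q2','Q3'")
    if (is.numeric(min) && is.numeric(max) && min > max)
      stop("constraint min must be <= max")
    structure(list(form = "interval", feature = feature, min = min, max = max),
              class = "ct_constraint")
  } else {
    if (is.null(left) || is.null(relation) || is.null(right))
      stop("comparison constraint needs left, relation and right")
    relation <- match.arg(relation, c("<", "<=", ">", ">="))
    structure(list(form = "comparison", left = left, relation = relation,
                   right = right), class = "ct_constraint")
  }
}

#' Cell-type definition
#'
#' A named, coloured conjunction of constraints. Types are evaluated in
#' definition order and a cell receives the first type whose constraints all
#' hold; relevant cells matching no type are labelled `"unknown"`.
#'
#' @param name Unique type name.
#' @param color Display colour (hex string).
#' @param constraints List of [constraint()] objects (at least one).
#' @return A `ct_celltype` list.
#' @export
cell_type <- function(name, color = "#808080", constraints) {
  if (!length(constraints)) stop("a cell type needs at least one constraint")
  stopifnot(all(vapply(constraints, inherits, logical(1), "ct_constraint")))
  structure(list(name = name, color = color, constraints = constraints),
            class = "ct_celltype")
}

check_feature_cols <- function(table, feats, what) {
  missing <- setdiff(feats, names(table))
  if (length(missing))
    stop(what, " references unknown feature(s): ",
         paste(missing, collapse = ", "), "; valid features: ",
         paste(grep("^M[123]\\.", names(table), value = TRUE), collapse = ", "))
}

#' Flag relevant cells
#'
#' A cell is relevant iff it satisfies every filter with inclusive bounds.
#' With no filters all cells are relevant.
#'
#' @param table A feature table from [marker1_features()].
#' @param filters List of [relevance_filter()] objects.
#' @return The table with its `relevant` column updated.
#' @export
apply_filters <- function(table, filters = list()) {
  rel <- rep(TRUE, nrow(table))
  for (f in filters) {
    stopifnot(inherits(f, "ct_filter"))
    check_feature_cols(table, f$feature, "relevance filter")
    v <- table[[f$feature]]
    rel <- rel & !is.na(v) & v >= f$min & v <= f$max
  }
  table$relevant <- rel
  table
}

#' Quartile thresholds of a feature over relevant cells
#'
#' Type-7 quartiles for use as constraint bounds: "in Q4" means
#' `value >= Q3`, "in Q1" means `value <= Q1`, interquartile means
#' `Q1 < value < Q3`.
#'
#' @param table A feature table with a `relevant` column.
#' @param feature Namespaced feature name.
#' @return Named numeric vector `c(Q1, Q2, Q3)`.
#' @export
quartile_thresholds <- function(table, feature) {
  check_feature_cols(table, feature, "quartile_thresholds")
  v <- table[[feature]][table$relevant]
  v <- v[!is.na(v)]
  if (length(v) < 4)
    stop("quartile thresholds need at least 4 relevant cells with '",
         feature, "' present (got ", length(v), ")")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(Q1 = q[1], Q2 = q[2], Q3 = q[3])
}

resolve_bound <- function(bound, table, feature) {
  if (is.numeric(bound)) return(bound)
  quartile_thresholds(table, feature)[[bound]]
}

#' Classify relevant cells into user-defined types
#'
#' Evaluates the type definitions in order on every relevant cell and assigns
#' the first type whose constraints are all satisfied (inclusive interval
#' bounds). Relevant cells matching no type are `"unknown"`; irrelevant cells
#' are `"excluded"`. A diagnostic `all_matching_types` column lists every
#' matching type (comma-separated) since definitions may overlap.
#'
#' @param table A feature table with a `relevant` column.
#' @param types List of [cell_type()] definitions (priority = order).
#' @return The table with `cell_type` and `all_matching_types` columns.
#' @export
classify_cells <- function(table, types = list()) {
  stopifnot(all(vapply(types, inherits, logical(1), "ct_celltype")))
  nms <- vapply(types, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("cell type names must be unique")
  n <- nrow(table)
  label <- ifelse(table$relevant, "unknown", "excluded")
  matches <- vector("list", n)
  for (ty in types) {
    ok <- rep(TRUE, n)
    for (cs in ty$constraints) {
      ok <- ok & evaluate_constraint(cs, table)
    }
    ok <- ok & table$relevant
    for (i in which(ok)) matches[[i]] <- c(matches[[i]], ty$name)
  }
  first <- vapply(matches, function(m) if (length(m)) m[1] else NA_character_,
                  character(1))
  label[!is.na(first)] <- first[!is.na(first)]
  table$cell_type <- label
  table$all_matching_types <- vapply(matches, paste, character(1), collapse = ",")
  table
}

evaluate_constraint <- function(cs, table) {
  if (cs$form == "interval") {
    check_feature_cols(table, cs$feature, "constraint")
    v <- table[[cs$feature]]
    lo <- resolve_bound(cs$min, table, cs$feature)
    hi <- resolve_bound(cs$max, table, cs$feature)
    !is.na(v) & v >= lo & v <= hi
  } else {
    check_feature_cols(table, c(cs$left, cs$right), "constraint")
    l <- table[[cs$left]]; r <- table[[cs$right]]
    res <- switch(cs$relation,
                  "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r)
    !is.na(res) & res
  }
}

#' Quadrant counts for a feature pair
#'
#' Thresholds on two features divide their plane into four quadrants; counts
#' are over relevant cells with both features present. A cell is "high" on an
#' axis iff its value is greater than or equal to the threshold.
#'
#' @param table A feature table with a `relevant` column.
#' @param feature_x,feature_y Namespaced feature names.
#' @param thr_x,thr_y Thresholds.
#' @return A `ct_quadrants` object: tibble of the four counts (`n_LL`: both
#'   low; `n_LH`: x low, y high; `n_HL`: x high, y low; `n_HH`: both high)
#'   with the configuration in attributes.
#' @export
quadrant_counts <- function(table, feature_x, feature_y, thr_x, thr_y) {
  check_feature_cols(table, c(feature_x, feature_y), "quadrant_counts")
  x <- table[[feature_x]]; y <- table[[feature_y]]
  keep <- table$relevant & !is.na(x) & !is.na(y)
  hx <- x[keep] >= thr_x; hy <- y[keep] >= thr_y
  out <- tibble::tibble(
    n_LL = sum(!hx & !hy), n_LH = sum(!hx & hy),
    n_HL = sum(hx & !hy), n_HH = sum(hx & hy))
  structure(out, class = c("ct_quadrants", class(out)),
            feature_x = feature_x, feature_y = feature_y,
            thr_x = thr_x, thr_y = thr_y)
}
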