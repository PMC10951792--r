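#' Fit a curve model to a feature pair
#'
#' Least-squares fits of the classical scatter models. `linear` and
#' `polynomial` are ordinary polynomial least squares; `power`
#' (`y = a * x^b`), `logarithmic` (`y = a + b * log(x)`) and `exponential`
#' (`y = a * exp(b * x)`) are fitted by log-linearization (documented: the
#' least-squares solution of the linearized model), with R-squared always
#' reported on the original scale.
#'
#' @param x,y Numeric vectors of equal length.
#' @param model One of `"linear"`, `"polynomial"`, `"power"`,
#'   `"logarithmic"`, `"exponential"`.
#' @param degree Polynomial degree (model `"polynomial"` only).
#' @return A `ct_fit` object with parameters, fitted values and R-squared;
#'   see [tidy.ct_fit()] and [glance.ct_fit()].
#' @examples
#' f <- fit_curve(0:5, 2 * exp(0.5 * (0:5)), model = "exponential")
#' glance(f)$r.squared
#' @export
fit_curve <- function(x, y, model = c("linear", "polynomial", "power",
                                      "logarithmic", "exponential"),
                      degree = 2) {
  model <- match.arg(model)
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  npar <- switch(model, linear = 2, polynomial = degree + 1, power = 2,
                 logarithmic = 2, exponential = 2)
  if (n < npar)
    stop("need at least ", npar, " points for model '", model, "' (got ", n, ")")
  if (model %in% c("power", "logarithmic") && any(x <= 0))
    stop("model '", model, "' requires x > 0; offending points: ",
         paste(which(x <= 0), collapse = ", "))
  if (model %in% c("power", "exponential") && any(y <= 0))
    stop("model '", model, "' requires y > 0; offending points: ",
         paste(which(y <= 0), collapse = ", "))
  fitted <- params <- NULL
  switch(model,
    linear = {
      fit <- stats::lm(y ~ x)
      params <- c(intercept = unname(stats::coef(fit)[1]),
                  slope = unname(stats::coef(fit)[2]))
      fitted <- stats::fitted(fit)
    },
    polynomial = {
      fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
      params <- stats::setNames(unname(stats::coef(fit)),
                                paste0("c", 0:degree))
      fitted <- stats::fitted(fit)
    },
    power = {
      fit <- stats::lm(log(y) ~ log(x))
      a <- exp(unname(stats::coef(fit)[1])); b <- unname(stats::coef(fit)[2])
      params <- c(a = a, b = b)
      fitted <- a * x^b
    },
    logarithmic = {
      fit <- stats::lm(y ~ log(x))
      params <- c(a = unname(stats::coef(fit)[1]),
                  b = unname(stats::coef(fit)[2]))
      fitted <- stats::fitted(fit)
    },
    exponential = {
      fit <- stats::lm(log(y) ~ x)
      a <- exp(unname(stats::coef(fit)[1])); b <- unname(stats::coef(fit)[2])
      params <- c(a = a, b = b)
      fitted <- a * exp(b * x)
    })
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(model = model, degree = if (model == "polynomial") degree else NA,
                 params = params, r_squared = r2, n = n,
                 data = tibble::tibble(x = x, y = y, fitted = fitted)),
            class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat(sprintf("<%s fit> n = %d, R^2 = %.6g\n", x$model, x$n, x$r_squared))
  print(x$params)
  invisible(x)
}

#' Tidy a fitted curve
#'
#' @param x A `ct_fit` from [fit_curve()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.ct_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row model summary of a fitted curve
#'
#' @param x A `ct_fit` from [fit_curve()].
#' @param ... Unused.
#' @return A tibble with `model`, `r.squared` and `n`.
#' @export
glance.ct_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r_squared, n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
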