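#' @title Variable transformations for the regression pipeline
#' @description Each transform returns a `transformed_variable`: the
#'   transformed values plus the parameters (Box-Cox lambda, standardization
#'   mean/SD) needed to invert it or to apply it to new data.
#' @name transforms
NULL

new_transformed <- function(values, kind, lambda = NA_real_,
                            center = NA_real_, scale = NA_real_) {
  structure(list(values = values, kind = kind, lambda = lambda,
                 center = center, scale = scale),
            class = "transformed_variable")
}

#' @export
print.transformed_variable <- function(x, ...) {
  cat(sprintf("<transformed_variable> kind=%s n=%d lambda=%s center=%.4g scale=%.4g\n",
              x$kind, length(x$values),
              ifelse(is.na(x$lambda), "-", format(x$lambda, digits = 4)),
              x$center, x$scale))
  invisible(x)
}

#' Natural log transform
#' @param x positive numeric values.
#' @return A `transformed_variable` with `values = log(x)`.
#' @export
log_transform <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("log_transform needs positive values; offending indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  new_transformed(log(x), "log")
}

# profile log-likelihood of the Box-Cox model at lambda
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  z <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(sum((z - mean(z))^2) / n) + (lambda - 1) * sum(log(x))
}

#' Box-Cox transform with profile-maximum-likelihood lambda
#'
#' `(x^lambda - 1) / lambda` (`log(x)` at `lambda = 0`); lambda is estimated
#' once by maximizing the profile log-likelihood over `[-3, 3]` with
#' golden-section refinement ([stats::optimize()]) and stored, so the same
#' transform can be reapplied across imputed data sets.
#'
#' @param x positive numeric values.
#' @param lambda fix lambda instead of estimating it.
#' @param interval search interval for lambda.
#' @return A `transformed_variable` with the estimated `lambda`.
#' @export
boxcox_transform <- function(x, lambda = NULL, interval = c(-3, 3)) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("boxcox_transform needs positive values; offending indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (is.null(lambda))
    lambda <- stats::optimize(function(l) boxcox_loglik(x, l),
                              interval = interval, maximum = TRUE,
                              tol = 1e-6)$maximum
  z <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  new_transformed(z, "boxcox", lambda = lambda)
}

#' Z-standardization (X - mean) / SD
#'
#' Sample SD (n - 1 denominator). The moments are stored so the identical
#' scaling can be reused across imputed data sets.
#'
#' @param x numeric values with positive SD.
#' @param center,scale reuse previously computed moments.
#' @return A `transformed_variable` with mean-0 / SD-1 `values`.
#' @export
z_standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale <= 0) stop("constant input cannot be standardized")
  new_transformed((x - center) / scale, "z", center = center, scale = scale)
}

#' Dichotomize at the sample median (strictly above = 1)
#'
#' Values strictly above the median are coded 1, values at or below it 0, so
#' the group-1 fraction is always <= 50%. Used for low-variability outcomes
#' analyzed by logistic regression.
#'
#' @param x non-constant numeric values.
#' @param median_value reuse a previously computed median.
#' @return Integer 0/1 vector with attribute `median`.
#' @export
dichotomize_median <- function(x, median_value = NULL) {
  if (length(unique(x)) < 2L) stop("constant input cannot be dichotomized")
  if (is.null(median_value)) median_value <- stats::median(x)
  out <- as.integer(x > median_value)
  attr(out, "median") <- median_value
  out
}
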