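#' @title Regression engines for the sex-difference analysis
#' @description Thin, contract-checked wrappers around [stats::lm()] and
#'   [stats::glm()] that return a standardized `effect_estimate` for the
#'   women-vs-men contrast (men are the reference category throughout).
#' @name regression
NULL

new_effect_estimate <- function(term, estimate, se, df, scale, model,
                                adjustment, conf_level = 0.95, pooled = FALSE,
                                extra = list()) {
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  est <- list(term = term, estimate = estimate, se = se, df = df,
              ci = c(low = estimate - q * se, high = estimate + q * se),
              scale = scale, model = model, adjustment = adjustment,
              conf_level = conf_level, pooled = pooled)
  est <- c(est, extra)
  class(est) <- "effect_estimate"
  est
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$scale == "or") {
    cat(sprintf("<effect_estimate> %s: OR %.3f (95%% CI %.3f to %.3f)%s\n",
                x$term, exp(x$estimate), exp(x$ci[1]), exp(x$ci[2]),
                if (x$pooled) " [pooled]" else ""))
  } else {
    cat(sprintf("<effect_estimate> %s: beta %.3f (95%% CI %.3f to %.3f)%s\n",
                x$term, x$estimate, x$ci[1], x$ci[2],
                if (x$pooled) " [pooled]" else ""))
  }
  invisible(x)
}

#' Odds ratio and CI of an effect estimate on the log-odds scale
#' @param est an `effect_estimate` with `scale = "or"`.
#' @return Named vector `or`, `low`, `high`.
#' @export
odds_ratio <- function(est) {
  stopifnot(inherits(est, "effect_estimate"), est$scale == "or")
  c(or = exp(est$estimate), low = unname(exp(est$ci[1])),
    high = unname(exp(est$ci[2])))
}

check_design <- function(design, outcome_len) {
  if (!is.data.frame(design)) stop("`design` must be a data.frame")
  if (nrow(design) != outcome_len) stop("design and outcome lengths differ")
  if (anyNA(design)) {
    bad <- names(design)[vapply(design, anyNA, logical(1))]
    stop("missing values in design columns: ", paste(bad, collapse = ", "),
         " (impute first)")
  }
}

#' Linear regression women-to-men contrast
#'
#' Ordinary least squares of a (typically Z-standardized) outcome on `sex`
#' plus the adjustment covariates; returns the woman-vs-man coefficient with
#' its Wald 95% CI (t distribution, residual df).
#'
#' @param outcome numeric outcome vector.
#' @param design data.frame of covariates; must contain `sex` (factor with
#'   reference level `"man"`) and no missing values.
#' @param contrast name of the design column whose effect is reported
#'   (default `"sex"`).
#' @param conf_level confidence level.
#' @return An `effect_estimate` (`scale = "beta"`).
#' @export
fit_linear <- function(outcome, design, contrast = "sex", conf_level = 0.95) {
  check_design(design, length(outcome))
  dat <- cbind(.y = outcome, design)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  term <- grep(paste0("^", contrast), rownames(sm), value = TRUE)
  if (length(term) != 1L)
    stop("contrast `", contrast, "` does not map to exactly one coefficient")
  new_effect_estimate(term, sm[term, 1], sm[term, 2], df = fit$df.residual,
                      scale = "beta", model = "linear",
                      adjustment = setdiff(names(design), contrast),
                      conf_level = conf_level,
                      extra = list(n = length(outcome), fit = fit))
}

#' Logistic regression women-to-men contrast
#'
#' Maximum-likelihood logistic fit of a binary outcome (above-median = 1) on
#' `sex` plus covariates. The estimate is kept on the log-odds scale with a
#' normal-theory Wald CI; [odds_ratio()] exponentiates. Complete or
#' quasi-complete separation is detected (non-converged fit or huge
#' coefficients) and reported as an error rather than silently penalized.
#'
#' @inheritParams fit_linear
#' @return An `effect_estimate` (`scale = "or"`, log-odds internally).
#' @export
fit_logistic <- function(outcome, design, contrast = "sex", conf_level = 0.95) {
  check_design(design, length(outcome))
  if (length(unique(outcome)) < 2L) stop("both outcome classes must be present")
  dat <- cbind(.y = outcome, design)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  sm <- summary(fit)$coefficients
  term <- grep(paste0("^", contrast), rownames(sm), value = TRUE)
  if (length(term) != 1L)
    stop("contrast `", contrast, "` does not map to exactly one coefficient")
  if (!fit$converged || any(abs(sm[, 1]) > 15))
    stop("possible complete separation: logistic fit unstable (|coef| > 15 or non-convergence)")
  new_effect_estimate(term, sm[term, 1], sm[term, 2], df = Inf,
                      scale = "or", model = "logistic",
                      adjustment = setdiff(names(design), contrast),
                      conf_level = conf_level,
                      extra = list(n = length(outcome), fit = fit))
}

#' Minimum sample size for the multiple-regression F test
#'
#' Power analysis for the overall F test of a linear model with `u`
#' predictors and Cohen's effect size `f2`, using the noncentral F
#' distribution with Cohen's noncentrality convention
#' `lambda = f2 * (u + v + 1)` where `v` is the denominator df. The
#' continuous `v` solving `power(v) = power` is found by root search and the
#' required number of subjects is reported as `u + v` rounded to the nearest
#' integer — the convention of the widely used `pwr`-style calculators this
#' reproduces. With `convention = "total-n"` the alternative convention
#' (smallest integer N with `lambda = f2 * N`, `v = N - u - 1`, power at
#' least the target) is used instead; it yields slightly larger N.
#'
#' @param u number of predictors (numerator df).
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param alpha type-I error level.
#' @param power target power.
#' @param convention `"cohen"` (default) or `"total-n"`, see Details.
#' @return Integer sample size, with attributes `v` (denominator df solution)
#'   and `power_achieved`.
#' @examples
#' required_sample_size(u = 8, f2 = 0.05)  # 307
#' @export
required_sample_size <- function(u, f2, alpha = 0.05, power = 0.80,
                                 convention = c("cohen", "total-n")) {
  convention <- match.arg(convention)
  stopifnot(u >= 1, alpha > 0, alpha < 1, power > 0, power < 1)
  if (!is.finite(f2) || f2 <= 1e-12)
    stop("effect size f2 is (near) zero: target power unreachable")
  pw_at_v <- function(v) 1 - stats::pf(stats::qf(1 - alpha, u, v), u, v,
                                       ncp = f2 * (u + v + 1))
  if (convention == "cohen") {
    if (pw_at_v(1e7) < power) stop("target power unreachable for this f2")
    v <- stats::uniroot(function(v) pw_at_v(v) - power,
                        lower = 2, upper = 1e7, tol = 1e-8)$root
    n <- as.integer(round(u + v))
    structure(n, v = v, power_achieved = pw_at_v(v))
  } else {
    pw_at_n <- function(n) 1 - stats::pf(stats::qf(1 - alpha, u, n - u - 1),
                                         u, n - u - 1, ncp = f2 * n)
    n <- u + 3
    while (pw_at_n(n) < power) {
      n <- n + 1L
      if (n > 1e7) stop("target power unreachable for this f2")
    }
    structure(as.integer(n), v = n - u - 1, power_achieved = pw_at_n(n))
  }
}
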