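#' Multiple imputation of missing smoking status by chained equations
#'
#' The analysis contract allows missingness only in the `smoking` column
#' (current / former / never). Each of the `m` chains runs `iterations`
#' sweeps; a sweep fits the imputation model on a bootstrap resample of the
#' complete rows (making the imputation "proper": parameter uncertainty is
#' propagated) and draws categories for the missing rows from the predicted
#' probabilities. The categorical model is a pair of nested binary logistic
#' regressions (current vs not, then former vs never), equivalent to a
#' sequential-logit multinomial model. With a single incomplete variable the
#' sweeps are stochastically independent; the final sweep's draw is kept.
#'
#' @param data data.frame; only `smoking` (factor) may contain `NA`.
#' @param m number of imputations (default 15).
#' @param iterations sweeps per chain (default 30).
#' @param seed integer seed; the whole set is deterministic given it.
#' @param predictors columns used in the imputation model (default: all
#'   others).
#' @return An object of class `imputation_set`: list with `completed`
#'   (list of m complete data.frames), `m`, `iterations`, `seed`,
#'   `missing_idx`, `model` (description string).
#' @export
impute_chained <- function(data, m = 15L, iterations = 30L, seed = 1L,
                           predictors = NULL) {
  stopifnot(is.data.frame(data), m >= 1L, iterations >= 1L)
  other_na <- vapply(data[setdiff(names(data), "smoking")], anyNA, logical(1))
  if (any(other_na))
    stop("missingness outside `smoking` is out of contract: ",
         paste(names(other_na)[other_na], collapse = ", "))
  if (!"smoking" %in% names(data)) stop("`data` must contain a `smoking` column")
  if (!is.factor(data$smoking)) data$smoking <- factor(data$smoking)
  miss <- which(is.na(data$smoking))
  if (is.null(predictors)) predictors <- setdiff(names(data), "smoking")

  completed <- vector("list", m)
  if (length(miss) == 0L) {
    for (i in seq_len(m)) completed[[i]] <- data
  } else {
    obs <- data[-miss, , drop = FALSE]
    lev <- levels(data$smoking)
    newx <- data[miss, predictors, drop = FALSE]
    with_seed(seed, {
      for (i in seq_len(m)) {
        filled <- data
        for (it in seq_len(iterations)) {
          boot <- obs[sample.int(nrow(obs), replace = TRUE), , drop = FALSE]
          filled$smoking[miss] <- draw_smoking(boot, newx, predictors, lev)
        }
        completed[[i]] <- filled
      }
    })
  }
  structure(list(completed = completed, m = m, iterations = iterations,
                 seed = seed, missing_idx = miss,
                 model = "bootstrap nested binary logits (current | former | never)"),
            class = "imputation_set")
}

# fit the nested logits on `boot` and draw categories for `newx`
draw_smoking <- function(boot, newx, predictors, lev) {
  fml <- function(y) stats::reformulate(predictors, response = y)
  boot$.cur <- as.integer(boot$smoking == lev[1])
  p_cur <- tryCatch({
    f1 <- suppressWarnings(stats::glm(fml(".cur"), data = boot, family = stats::binomial()))
    as.numeric(stats::predict(f1, newdata = newx, type = "response"))
  }, error = function(e) rep(mean(boot$.cur), nrow(newx)))
  nb <- boot[boot$.cur == 0L, , drop = FALSE]
  nb$.for <- as.integer(nb$smoking == lev[2])
  p_for <- tryCatch({
    if (length(unique(nb$.for)) < 2L) rep(mean(nb$.for), nrow(newx))
    else {
      f2 <- suppressWarnings(stats::glm(fml(".for"), data = nb, family = stats::binomial()))
      as.numeric(stats::predict(f2, newdata = newx, type = "response"))
    }
  }, error = function(e) rep(mean(nb$.for), nrow(newx)))
  u1 <- stats::runif(nrow(newx))
  u2 <- stats::runif(nrow(newx))
  out <- ifelse(u1 < p_cur, lev[1], ifelse(u2 < p_for, lev[2], lev[3]))
  factor(out, levels = lev)
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m=%d, %d iterations, %d missing value(s), seed=%d\n",
              x$m, x$iterations, length(x$missing_idx), x$seed))
  invisible(x)
}

#' Pool effect estimates across imputations with Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation estimates; total
#' variance `T = Wbar + (1 + 1/m) * B` with `Wbar` the mean within-imputation
#' variance and `B` the between-imputation variance. The CI uses a t
#' distribution with Barnard-Rubin adjusted degrees of freedom (reducing to
#' the classic Rubin df when the complete-data df is infinite, and to the
#' complete-data df when `B = 0`).
#'
#' @param estimates list of `effect_estimate`s on a common scale (all `beta`
#'   or all log-odds).
#' @param conf_level confidence level for the pooled CI.
#' @return A pooled `effect_estimate` with extra fields `m`, `within`,
#'   `between`, `fmi` (fraction of missing information).
#' @export
pool_rubin <- function(estimates, conf_level = 0.95) {
  stopifnot(length(estimates) >= 1L)
  scales <- vapply(estimates, function(e) e$scale, character(1))
  if (length(unique(scales)) != 1L)
    stop("cannot pool estimates on mixed scales: ", paste(unique(scales), collapse = ", "))
  m <- length(estimates)
  q <- vapply(estimates, function(e) e$estimate, numeric(1))
  w <- vapply(estimates, function(e) e$se^2, numeric(1))
  qbar <- mean(q)
  wbar <- mean(w)
  b <- if (m > 1L) stats::var(q) else 0
  tvar <- wbar + (1 + 1 / m) * b
  nu_com <- estimates[[1]]$df
  if (b <= 0 || m == 1L) {
    df <- nu_com
  } else {
    lam <- (1 + 1 / m) * b / tvar
    nu_old <- (m - 1) / lam^2
    df <- if (is.finite(nu_com)) {
      nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lam)
      nu_old * nu_obs / (nu_old + nu_obs)
    } else nu_old
  }
  new_effect_estimate(estimates[[1]]$term, qbar, sqrt(tvar), df = df,
                      scale = estimates[[1]]$scale, model = estimates[[1]]$model,
                      adjustment = estimates[[1]]$adjustment,
                      conf_level = conf_level, pooled = TRUE,
                      extra = list(m = m, within = wbar, between = b,
                                   fmi = if (tvar > 0) (1 + 1 / m) * b / tvar else 0))
}
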