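# Multiple imputation and Rubin's-rules pooling.

sim_smoking_data <- function(n = 326, miss = 7, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    sex = factor(sample(c("man", "woman"), n, TRUE, prob = c(0.27, 0.73)),
                 levels = c("man", "woman")),
    age = rnorm(n, 58, 12),
    smoking = factor(sample(c("current", "former", "never"), n, TRUE,
                            prob = c(0.43, 0.32, 0.26)),
                     levels = c("current", "former", "never")))
  if (miss > 0) d$smoking[sample.int(n, miss)] <- NA
  d
}

test_that("impute_chained: zero missingness returns the input m times", {
  d <- sim_smoking_data(miss = 0)
  imp <- impute_chained(d, m = 5, iterations = 3, seed = 1)
  expect_length(imp$completed, 5)
  for (tab in imp$completed) expect_identical(tab, d)
})

test_that("impute_chained is deterministic and fills only the missing entries", {
  d <- sim_smoking_data(miss = 7)
  imp1 <- impute_chained(d, m = 4, iterations = 5, seed = 42)
  imp2 <- impute_chained(d, m = 4, iterations = 5, seed = 42)
  expect_identical(imp1$completed, imp2$completed)
  expect_equal(imp1$missing_idx, which(is.na(d$smoking)))
  obs <- which(!is.na(d$smoking))
  for (tab in imp1$completed) {
    expect_false(anyNA(tab$smoking))
    expect_identical(tab$smoking[obs], d$smoking[obs])  # observed untouched
    expect_identical(tab[names(tab) != "smoking"], d[names(d) != "smoking"])
  }
  # at least two chains should disagree somewhere (it is stochastic)
  draws <- sapply(imp1$completed, function(tab) as.integer(tab$smoking[imp1$missing_idx]))
  expect_gt(length(unique(as.vector(draws))), 1)
})

test_that("MCAR imputation reproduces observed category frequencies", {
  d <- sim_smoking_data(n = 4000, miss = 400, seed = 9)
  imp <- impute_chained(d, m = 10, iterations = 2, seed = 5)
  obs_freq <- prop.table(table(d$smoking[!is.na(d$smoking)]))
  imp_freq <- prop.table(table(unlist(lapply(imp$completed, function(tab)
    as.character(tab$smoking[imp$missing_idx])))))
  n_imp <- 400 * 10
  for (lev in names(obs_freq)) {
    se <- sqrt(obs_freq[[lev]] * (1 - obs_freq[[lev]]) / n_imp) +
      sqrt(obs_freq[[lev]] * (1 - obs_freq[[lev]]) / 3600)
    expect_lt(abs(imp_freq[[lev]] - obs_freq[[lev]]), 3 * se + 0.01)
  }
})

test_that("impute_chained rejects out-of-contract missingness", {
  d <- sim_smoking_data(miss = 5)
  d$age[3] <- NA
  expect_error(impute_chained(d), "out of contract")
})

test_that("pool_rubin reproduces hand-computed Rubin arithmetic", {
  mk <- function(est, se) aneumorph:::new_effect_estimate(
    "sexwoman", est, se, df = 100, scale = "beta", model = "linear",
    adjustment = character(0))
  # m=2, estimates 1.0 and 2.0, each SE^2 = 0.04:
  # W = 0.04, B = 0.5, T = 0.04 + 1.5*0.5 = 0.79, pooled = 1.5
  pooled <- pool_rubin(list(mk(1.0, 0.2), mk(2.0, 0.2)))
  expect_equal(pooled$estimate, 1.5)
  expect_equal(pooled$within, 0.04)
  expect_equal(pooled$between, 0.5)
  expect_equal(pooled$se^2, 0.79)
  expect_true(pooled$pooled)
  # identical estimates -> pooled = that estimate, B = 0, df = complete-data df
  same <- pool_rubin(list(mk(0.7, 0.1), mk(0.7, 0.1), mk(0.7, 0.1)))
  expect_equal(same$estimate, 0.7)
  expect_equal(same$between, 0)
  expect_equal(same$se, 0.1)
  expect_equal(same$df, 100)
  # pooled SE >= sqrt(Wbar) always
  set.seed(12)
  for (rep in 1:20) {
    ests <- lapply(1:5, function(i) mk(rnorm(1), runif(1, 0.05, 0.3)))
    p <- pool_rubin(ests)
    expect_gte(p$se, sqrt(p$within))
  }
  # mixed scales rejected
  or_est <- aneumorph:::new_effect_estimate("sexwoman", 0.5, 0.2, df = Inf,
                                            scale = "or", model = "logistic",
                                            adjustment = character(0))
  expect_error(pool_rubin(list(mk(1, 0.1), or_est)), "mixed scales")
})

test_that("Barnard-Rubin df is finite, positive and below both limits", {
  mk <- function(est, se, df) aneumorph:::new_effect_estimate(
    "sexwoman", est, se, df = df, scale = "beta", model = "linear",
    adjustment = character(0))
  pooled <- pool_rubin(list(mk(0.2, 0.1, 50), mk(0.5, 0.12, 50), mk(0.35, 0.11, 50)))
  expect_true(is.finite(pooled$df) && pooled$df > 0)
  expect_lt(pooled$df, 50)  # never exceeds the complete-data df
  # infinite complete-data df falls back to classic Rubin df
  pooled_inf <- pool_rubin(list(mk(0.2, 0.1, Inf), mk(0.5, 0.12, Inf)))
  lam <- (1 + 1 / 2) * pooled_inf$between / pooled_inf$se^2
  expect_equal(pooled_inf$df, (2 - 1) / lam^2)
})
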