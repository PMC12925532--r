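# Regression engines and the power calculation.

test_that("fit_linear equals the closed-form least-squares solution", {
  # 6-row hand-built design
  design <- data.frame(sex = factor(c("man", "man", "man", "woman", "woman", "woman"),
                                    levels = c("man", "woman")),
                       age = c(50, 60, 70, 45, 55, 65))
  y <- c(0.2, -0.1, 0.4, 0.9, 0.6, 1.1)
  est <- fit_linear(y, design)
  X <- cbind(1, as.integer(design$sex == "woman"), design$age)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(est$estimate, beta[2, 1], tolerance = 1e-12)
  sigma2 <- sum((y - X %*% beta)^2) / (6 - 3)
  se <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
  expect_equal(est$se, se, tolerance = 1e-12)
  expect_equal(unname(est$ci["low"]), est$estimate - qt(0.975, 3) * est$se)
})

test_that("fit_linear: null case, simulation recovery, rank deficiency", {
  set.seed(10)
  sex <- factor(sample(c("man", "woman"), 200, replace = TRUE), levels = c("man", "woman"))
  y0 <- rep(c(0.3, 0.3), 100)[seq_along(sex)]  # identical across sexes
  est0 <- suppressWarnings(fit_linear(y0 + 0, data.frame(sex = sex)))  # perfect fit
  expect_equal(est0$estimate, 0, tolerance = 1e-12)
  # beta_true = -0.30 at n = 10000 recovered within 3 SE
  n <- 10000
  sex <- factor(ifelse(runif(n) < 0.73, "woman", "man"), levels = c("man", "woman"))
  y <- -0.30 * (sex == "woman") + rnorm(n)
  est <- fit_linear(y, data.frame(sex = sex))
  expect_lt(abs(est$estimate + 0.30), 3 * est$se)
  # duplicated column -> rank deficiency reported
  d <- data.frame(sex = sex, a = as.integer(sex == "woman"))
  expect_error(fit_linear(y, d), "rank-deficient")
  # missing values rejected with column name
  d2 <- data.frame(sex = sex, age = c(NA, rnorm(n - 1)))
  expect_error(fit_linear(y, d2), "age")
})

test_that("fit_logistic equals the 2x2 cross-product OR and detects separation", {
  # a=10 (women,1), b=5 (women,0), c=4 (men,1), d=8 (men,0) -> OR 4.0
  sex <- factor(c(rep("woman", 15), rep("man", 12)), levels = c("man", "woman"))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 8))
  est <- fit_logistic(y, data.frame(sex = sex))
  expect_equal(unname(odds_ratio(est)["or"]), 4.0, tolerance = 1e-6)
  expect_equal(est$estimate, log(4), tolerance = 1e-6)
  # independence -> OR ~ 1, CI covers 1
  set.seed(11)
  n <- 5000
  sex <- factor(sample(c("man", "woman"), n, replace = TRUE), levels = c("man", "woman"))
  y <- rbinom(n, 1, 0.5)
  est <- fit_logistic(y, data.frame(sex = sex))
  or <- odds_ratio(est)
  expect_lt(abs(est$estimate), 3 * est$se)
  expect_true(or["low"] < 1 && or["high"] > 1)
  # log-OR ln(2.38) recovered at n = 10000 with a balanced covariate
  n <- 10000
  sex <- factor(ifelse(runif(n) < 0.5, "woman", "man"), levels = c("man", "woman"))
  age <- rnorm(n)
  p <- plogis(-0.2 + log(2.38) * (sex == "woman") + 0.3 * age)
  y <- rbinom(n, 1, p)
  est <- fit_logistic(y, data.frame(sex = sex, age = age))
  expect_lt(abs(est$estimate - log(2.38)), 3 * est$se)
  # complete separation detected
  ysep <- as.integer(sex == "woman")
  suppressWarnings(expect_error(fit_logistic(ysep, data.frame(sex = sex)), "separation"))
  expect_error(fit_logistic(rep(1, 10),
                            data.frame(sex = factor(rep(c("man", "woman"), 5)))),
               "classes")
})

test_that("required_sample_size reproduces 307 and behaves monotonically", {
  n <- required_sample_size(u = 8, f2 = 0.05, alpha = 0.05, power = 0.80)
  expect_identical(as.integer(n), 307L)
  # the continuous denominator-df solution achieves the target power exactly
  v <- attr(n, "v")
  pw <- 1 - pf(qf(0.95, 8, v), 8, v, ncp = 0.05 * (8 + v + 1))
  expect_equal(pw, 0.80, tolerance = 1e-6)
  # larger effect -> smaller N
  expect_lt(required_sample_size(8, 0.10), n)
  # more predictors -> larger N
  expect_gt(required_sample_size(12, 0.05), n)
  # total-N convention: smallest integer N whose own power passes the target
  n2 <- required_sample_size(8, 0.05, convention = "total-n")
  pw_at <- function(N) 1 - pf(qf(0.95, 8, N - 9), 8, N - 9, ncp = 0.05 * N)
  expect_gte(pw_at(n2), 0.80)
  expect_lt(pw_at(n2 - 1L), 0.80)
  expect_error(required_sample_size(8, 0), "zero")
})
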