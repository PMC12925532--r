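# Cohort simulator: marginals, missingness mechanisms, selection, exclusions.

test_that("generate_cohort is deterministic and matches requested marginals", {
  coh1 <- generate_cohort(sim_params(seed = 5))
  coh2 <- generate_cohort(sim_params(seed = 5))
  expect_identical(coh1, coh2)
  expect_false(identical(coh1$age, generate_cohort(sim_params(seed = 6))$age))
  # every patient has >= 1 aneurysm and ids are 1..n
  expect_setequal(unique(coh1$patient_id), seq_len(326))

  big <- generate_cohort(sim_params(n = 10000L, seed = 1))
  pat <- big[!duplicated(big$patient_id), ]
  n <- nrow(pat)
  se_p <- function(p) sqrt(p * (1 - p) / n)
  # proportion women within 3 SE of 0.733
  expect_lt(abs(mean(pat$sex == "woman") - 239 / 326), 3 * se_p(239 / 326))
  # age means by sex
  w <- pat$sex == "woman"
  expect_lt(abs(mean(pat$age[w]) - 58), 3 * 12 / sqrt(sum(w)))
  expect_lt(abs(mean(pat$age[!w]) - 61), 3 * 13 / sqrt(sum(!w)))
  # hypertension, modality, multiplicity by sex
  expect_lt(abs(mean(pat$hypertension[w]) - 126 / 239), 3 * se_p(126 / 239))
  expect_lt(abs(mean(pat$modality[!w] == "CTA") - 53 / 87), 3 * se_p(53 / 87) * 2)
  expect_lt(abs(mean(pat$n_aneurysms[w] > 1) - 107 / 239), 3 * se_p(107 / 239))
  # every smoking / location category within 3 SE of its target
  for (lev in c("current", "former", "never")) {
    p0 <- c(current = 106, former = 69, never = 64)[lev] / 239
    expect_lt(abs(mean(pat$smoking[w] == lev) - p0), 3 * sqrt(p0 * (1 - p0) / sum(w)))
  }
  for (lev in c("ACA/ACom", "ICA", "PCom", "MCA", "Posterior")) {
    p0 <- c(`ACA/ACom` = 40, ICA = 50, PCom = 19, MCA = 90, Posterior = 40)[lev] / 239
    expect_lt(abs(mean(pat$location[w] == lev) - p0), 3 * sqrt(p0 * (1 - p0) / sum(w)))
  }
  # size: log-normal medians per sex
  expect_lt(abs(median(pat$size_mm[w]) - 5.4), 0.2)
  expect_lt(abs(median(pat$size_mm[!w]) - 6.3), 0.5)
})

test_that("configured sex effect appears in the simulated standardized difference", {
  params <- sim_params(n = 10000L,
                       sex_effects = c(volume = -0.30, sphericity = 0, elongation = 0,
                                       flatness = 0, shape_index = 0, curvedness = 0),
                       seed = 2)
  coh <- select_index_aneurysm(generate_cohort(params))
  z <- z_standardize(log(coh$volume_mm3))$values
  # the volume model is never size-adjusted (size is the same construct)
  est <- fit_linear(z, data.frame(
    sex = coh$sex, age = coh$age, hypertension = coh$hypertension,
    smoking_ever = as.integer(coh$smoking != "never"),
    location = coh$location, modality = coh$modality))
  expect_lt(abs(est$estimate + 0.30), 3 * est$se + 0.02)
})

test_that("inject_missing: rates, mechanisms and MAR log-odds", {
  coh <- generate_cohort(sim_params(seed = 3))
  expect_identical(inject_missing(coh, rate = 0), coh)
  # rate 0.02 on n=326: expected ~7 missing patients (binomial)
  counts <- sapply(1:200, function(s) {
    ci <- inject_missing(coh, rate = 0.02, mechanism = "MCAR", seed = s)
    length(attr(ci, "missing_patients"))
  })
  expect_lt(abs(mean(counts) - 326 * 0.02), 3 * sqrt(326 * 0.02 * 0.98 / 200))
  # MAR: the configured sex log-odds is recovered by a logistic fit
  big <- generate_cohort(sim_params(n = 30000L, seed = 4))
  bm <- inject_missing(big, rate = 0.05, mechanism = "MAR",
                       mar_logodds = c(woman = 0.8), seed = 9)
  pat <- bm[!duplicated(bm$patient_id), ]
  fit <- glm(is.na(smoking) ~ sex, data = pat, family = binomial())
  co <- summary(fit)$coefficients
  expect_lt(abs(co["sexwoman", 1] - 0.8), 3 * co["sexwoman", 2])
  # MCAR: complete-case and full-cohort age means agree within noise
  cm <- inject_missing(big, rate = 0.3, mechanism = "MCAR", seed = 10)
  pat2 <- cm[!duplicated(cm$patient_id), ]
  expect_lt(abs(mean(pat2$age[!is.na(pat2$smoking)]) - mean(pat2$age)),
            3 * sd(pat2$age) / sqrt(sum(!is.na(pat2$smoking))))
  expect_error(inject_missing(coh, rate = 0.7), "rate")
})

test_that("select_index_aneurysm keeps the largest with documented tie-break", {
  coh <- data.frame(patient_id = c(1, 1, 2, 3, 3),
                    aneurysm_id = c(1, 2, 1, 1, 2),
                    size_mm = c(3.2, 7.1, 4.0, 5.0, 5.0))
  sel <- select_index_aneurysm(coh)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$size_mm[sel$patient_id == 1], 7.1)
  expect_equal(sel$aneurysm_id[sel$patient_id == 2], 1)     # single: unchanged
  expect_equal(sel$aneurysm_id[sel$patient_id == 3], 1)     # tie: first record
  expect_equal(attr(sel, "ties"), 3L)
  # real cohort: one row per patient, each the patient's max
  big <- generate_cohort(sim_params(n = 500L, seed = 7))
  sel2 <- select_index_aneurysm(big)
  expect_equal(nrow(sel2), 500)
  mx <- tapply(big$size_mm, big$patient_id, max)
  expect_equal(as.numeric(mx[as.character(sel2$patient_id)]), sel2$size_mm)
})

test_that("apply_exclusions: flow accounting always balances", {
  coh <- generate_cohort(sim_params(n = 416L, seed = 8))
  ids <- unique(coh$patient_id)
  flags <- data.frame(patient_id = ids,
                      non_saccular = ids <= 30,
                      thrombus = ids > 30 & ids <= 50,
                      calcification = ids > 50 & ids <= 70,
                      image_quality = ids > 70 & ids <= 80,
                      opt_out = ids > 80 & ids <= 90)
  res <- apply_exclusions(coh, flags)
  expect_equal(res$flow$sampled, 416)
  expect_equal(res$flow$excluded, 90)
  expect_equal(res$flow$included, 326)
  expect_equal(res$flow$sampled, res$flow$excluded + res$flow$included)
  expect_equal(length(unique(res$cohort$patient_id)), 326)
  # no flags -> included = sampled
  none <- flags; none[-1] <- FALSE
  expect_equal(apply_exclusions(coh, none)$flow$included, 416)
  # all flagged -> empty cohort with warning
  all_f <- flags; all_f$opt_out <- TRUE
  expect_warning(res2 <- apply_exclusions(coh, all_f), "empty")
  expect_equal(res2$flow$included, 0)
})
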