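#' Simulation parameters for a synthetic UIA patient cohort
#'
#' Defaults reproduce the marginal covariate structure of the reference
#' cohort: n = 326 patients, 73% women, age 58 (SD 12) years in women and
#' 61 (13) in men, sex-specific hypertension, smoking, aneurysm-location and
#' imaging-modality frequencies, log-normal aneurysm size (median 5.4 mm in
#' women, 6.3 mm in men), 41% of patients with multiple aneurysms, and about
#' 2% missing smoking status (missing-at-random, more often in women).
#'
#' Morphology is simulated directly on the analysis scales — log-volume and
#' the five shape parameters, each as a latent variable with marginal SD
#' close to 1 — with configurable women-vs-men effects in SD units
#' (`sex_effects`; positive = higher in women) plus modest covariate effects
#' so that confounding adjustment is exercised. Latents are back-transformed
#' onto the raw scales (mm^3 for volume; unitless fractions for sphericity /
#' elongation / flatness / shape index; mm^-1 for curvedness) using the
#' reference cohort's medians and IQR-derived spreads.
#'
#' @param n number of patients.
#' @param p_women proportion of women.
#' @param sex_effects named vector of women-vs-men effects in SD units, names
#'   `volume`, `sphericity`, `elongation`, `flatness`, `shape_index`,
#'   `curvedness`. Defaults are the reference univariable estimates.
#' @param missing_rate target smoking missingness rate.
#' @param missing_mechanism `"MAR"` (depends on sex) or `"MCAR"`.
#' @param seed default seed used by [generate_cohort()].
#' @param ... override any other component (see the function body for the
#'   full list: `age`, `hypertension`, `smoking`, `location`, `modality`,
#'   `size`, `multiple`, `covariate_effects`, `resid_sd`, `raw_maps`,
#'   `mar_logodds`).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n = 326L,
                       p_women = 239 / 326,
                       sex_effects = c(volume = -0.33, sphericity = 0.38,
                                       elongation = 0.05, flatness = -0.08,
                                       shape_index = 0.37, curvedness = -0.20),
                       missing_rate = 0.02,
                       missing_mechanism = c("MAR", "MCAR"),
                       seed = 1L, ...) {
  missing_mechanism <- match.arg(missing_mechanism)
  p <- list(
    n = as.integer(n), p_women = p_women,
    age = list(woman = c(mean = 58, sd = 12), man = c(mean = 61, sd = 13)),
    hypertension = c(woman = 126 / 239, man = 59 / 87),
    smoking = rbind(woman = c(current = 106, former = 69, never = 64) / 239,
                    man = c(current = 33, former = 34, never = 20) / 87),
    location = rbind(woman = c(`ACA/ACom` = 40, ICA = 50, PCom = 19,
                               MCA = 90, Posterior = 40) / 239,
                     man = c(`ACA/ACom` = 27, ICA = 11, PCom = 7,
                             MCA = 32, Posterior = 10) / 87),
    modality = c(woman = 141 / 239, man = 53 / 87),     # P(CTA)
    size = list(woman = c(meanlog = log(5.4), sdlog = log(8.0 / 3.5) / (2 * stats::qnorm(0.75))),
                man = c(meanlog = log(6.3), sdlog = log(9.3 / 4.5) / (2 * stats::qnorm(0.75)))),
    multiple = c(woman = 107 / 239, man = 27 / 87),      # P(>1 aneurysm)
    sex_effects = sex_effects,
    # shared covariate effects on each standardized latent (SD units)
    covariate_effects = list(age10 = 0.05, hypertension = 0.10,
                             smoking_ever = 0.10, zlogsize = 0.15,
                             zlogsize_volume = 0.70,
                             location = c(ICA = 0.05, PCom = 0.10,
                                          MCA = -0.05, Posterior = 0.10),
                             cta = 0.05),
    # residual SDs sized so the marginal latent SD is ~1
    resid_sd = c(volume = 0.67, sphericity = 0.97, elongation = 0.97,
                 flatness = 0.97, shape_index = 0.97, curvedness = 0.97),
    # back-transform maps: latent y -> raw scale
    raw_maps = list(
      volume = c(meanlog = log(77), sdlog = log(246 / 25) / (2 * stats::qnorm(0.75))),
      sphericity = c(center = 0.79, sd = 0.06 / (2 * stats::qnorm(0.75))),
      elongation = c(center = 0.88, sd = 0.10 / (2 * stats::qnorm(0.75))),
      flatness = c(center = 0.81, sd = 0.09 / (2 * stats::qnorm(0.75))),
      shape_index = c(center = 0.32, sd = 0.30 / (2 * stats::qnorm(0.75))),
      curvedness = c(center = 2.40, sd = 0.25 / (2 * stats::qnorm(0.75)))),
    missing_rate = missing_rate,
    missing_mechanism = missing_mechanism,
    mar_logodds = c(woman = 0.8),
    seed = as.integer(seed))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown sim_params components: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  for (pr in list(p$p_women, p$hypertension, p$modality, p$multiple))
    if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  for (mat in list(p$smoking, p$location)) {
    if (any(mat < 0)) stop("category probabilities must be non-negative")
    if (any(abs(rowSums(mat) - 1) > 1e-6)) stop("category probabilities must sum to 1")
  }
  structure(p, class = "sim_params")
}

outcome_names <- function() c("volume", "sphericity", "elongation", "flatness",
                              "shape_index", "curvedness")

#' Simulate a patient cohort with known sex effects on morphology
#'
#' One row per aneurysm (patients with multiple aneurysms contribute 2-3
#' rows); [select_index_aneurysm()] reduces to one row per patient. The
#' returned columns are the raw analysis inputs: `sex` (factor, reference
#' `man`), `age`, `hypertension`, `smoking` (current/former/never), 5-level
#' `location`, `modality`, per-aneurysm `size_mm`, and the six raw-scale
#' morphology columns `volume_mm3`, `sphericity`, `elongation`, `flatness`,
#' `shape_index`, `curvedness`.
#'
#' @param params a [sim_params()].
#' @param seed overrides `params$seed`.
#' @return A `cohort_table` data.frame with attributes `params` and `seed`.
#' @export
generate_cohort <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, {
    n <- params$n
    woman <- stats::rbinom(n, 1, params$p_women)
    sex <- factor(ifelse(woman == 1, "woman", "man"), levels = c("man", "woman"))
    pick <- function(w, m) ifelse(woman == 1, w, m)
    age <- stats::rnorm(n, pick(params$age$woman["mean"], params$age$man["mean"]),
                        pick(params$age$woman["sd"], params$age$man["sd"]))
    hypertension <- stats::rbinom(n, 1, pick(params$hypertension["woman"],
                                             params$hypertension["man"]))
    draw_cat <- function(probmat) {
      lev <- colnames(probmat)
      out <- character(n)
      for (s in c("woman", "man")) {
        idx <- which((woman == 1) == (s == "woman"))
        if (length(idx))
          out[idx] <- sample(lev, length(idx), replace = TRUE, prob = probmat[s, ])
      }
      factor(out, levels = lev)
    }
    smoking <- draw_cat(params$smoking)
    location <- draw_cat(params$location)
    modality <- factor(ifelse(stats::rbinom(n, 1, pick(params$modality["woman"],
                                                       params$modality["man"])) == 1,
                              "CTA", "MRA"), levels = c("MRA", "CTA"))
    n_an <- ifelse(stats::rbinom(n, 1, pick(params$multiple["woman"],
                                            params$multiple["man"])) == 1,
                   2L + stats::rbinom(n, 1, 0.25), 1L)

    rows <- rep(seq_len(n), n_an)
    meanlog_i <- pick(params$size$woman["meanlog"], params$size$man["meanlog"])[rows]
    sdlog_i <- pick(params$size$woman["sdlog"], params$size$man["sdlog"])[rows]
    size_mm <- stats::rlnorm(length(rows), meanlog_i, sdlog_i)
    zlogsize <- (log(size_mm) - log(5.8)) / 0.6
    # Size deviation feeding the volume latent, centered per sex and per
    # aneurysm count so the *index* (largest) aneurysm's expected size
    # contribution is sex-neutral: E[max of k standard normals] = 0, 1/sqrt(pi),
    # 1.5/sqrt(pi) for k = 1..3. Without this centering the configured sex
    # effect on volume (whose model is not size-adjusted) would be distorted
    # by the sex differences in size and multiplicity.
    delta_k <- c(0, 1 / sqrt(pi), 1.5 / sqrt(pi))[n_an[rows]]
    z_vol_size <- (log(size_mm) - meanlog_i) / sdlog_i - delta_k

    ce <- params$covariate_effects
    base_eta <- ce$age10 * (age[rows] - 58) / 10 +
      ce$hypertension * hypertension[rows] +
      ce$smoking_ever * as.integer(smoking[rows] != "never") +
      ifelse(location[rows] == "ACA/ACom", 0, ce$location[as.character(location[rows])]) +
      ce$cta * as.integer(modality[rows] == "CTA")

    out <- data.frame(patient_id = rows,
                      aneurysm_id = stats::ave(rows, rows, FUN = seq_along),
                      sex = sex[rows], age = age[rows],
                      hypertension = hypertension[rows],
                      smoking = smoking[rows], location = location[rows],
                      modality = modality[rows], size_mm = size_mm,
                      n_aneurysms = n_an[rows])
    for (oc in outcome_names()) {
      size_term <- if (oc == "volume") ce$zlogsize_volume * z_vol_size
                   else ce$zlogsize * zlogsize
      y <- params$sex_effects[[oc]] * woman[rows] + base_eta +
        size_term +
        stats::rnorm(length(rows), 0, params$resid_sd[[oc]])
      mp <- params$raw_maps[[oc]]
      raw <- if (oc == "volume") exp(mp["meanlog"] + mp["sdlog"] * y)
             else mp["center"] + mp["sd"] * y
      raw <- switch(oc,
        volume = raw,
        sphericity = pmin(pmax(raw, 0.05), 0.999),
        elongation = pmin(pmax(raw, 0.05), 1),
        flatness = pmin(pmax(raw, 0.02), 1),
        shape_index = pmin(pmax(raw, -1), 1),
        curvedness = pmax(raw, 0.01))
      out[[if (oc == "volume") "volume_mm3" else oc]] <- as.numeric(raw)
    }
    # enforce flatness <= elongation (axis-length ordering)
    out$flatness <- pmin(out$flatness, out$elongation)
    structure(out, params = params, seed = seed,
              class = c("cohort_table", "data.frame"))
  })
}

#' Set smoking status missing (MCAR or MAR)
#'
#' MAR missingness depends only on observed covariates: the default
#' mechanism adds `mar_logodds["woman"]` to the log-odds of missingness for
#' women (supported covariates: `woman`, `age10` = (age-58)/10,
#' `hypertension`). The intercept is calibrated by root search so the
#' expected rate over the realized covariates equals `rate`. Smoking is a
#' patient-level covariate, so all rows of a selected patient become `NA`.
#'
#' @param cohort a `cohort_table`.
#' @param rate fraction of patients with missing smoking, in `[0, 0.5)`.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param mar_logodds named log-odds increments for the MAR mechanism.
#' @param seed RNG seed.
#' @return The cohort with `NA`s injected; attribute `missing_patients`.
#' @export
inject_missing <- function(cohort, rate = 0.02,
                           mechanism = c("MAR", "MCAR"),
                           mar_logodds = c(woman = 0.8), seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(rate >= 0, rate < 0.5)
  if (rate == 0) return(cohort)
  pat <- !duplicated(cohort$patient_id)
  pdat <- cohort[pat, , drop = FALSE]
  np <- nrow(pdat)
  with_seed(seed, {
    if (mechanism == "MCAR") {
      miss <- stats::rbinom(np, 1, rate) == 1
    } else {
      lp <- rep(0, np)
      if (!is.na(mar_logodds["woman"]))
        lp <- lp + mar_logodds["woman"] * as.integer(pdat$sex == "woman")
      if (!is.na(mar_logodds["age10"]))
        lp <- lp + mar_logodds["age10"] * (pdat$age - 58) / 10
      if (!is.na(mar_logodds["hypertension"]))
        lp <- lp + mar_logodds["hypertension"] * pdat$hypertension
      alpha <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) - rate,
                              c(-30, 10))$root
      miss <- stats::runif(np) < stats::plogis(alpha + lp)
    }
    ids <- pdat$patient_id[miss]
    cohort$smoking[cohort$patient_id %in% ids] <- NA
    attr(cohort, "missing_patients") <- ids
    cohort
  })
}

#' Keep one aneurysm per patient: the largest
#'
#' The aneurysm with maximal `size_mm` is retained per patient; exact ties
#' are broken in favour of the first-annotated (lowest `aneurysm_id`), and
#' tied patients are recorded in the `ties` attribute.
#'
#' @param cohort a `cohort_table` (>= 1 aneurysm per patient).
#' @return A `cohort_table` with exactly one row per patient.
#' @export
select_index_aneurysm <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  o <- order(cohort$patient_id, -cohort$size_mm, cohort$aneurysm_id)
  srt <- cohort[o, , drop = FALSE]
  keep <- !duplicated(srt$patient_id)
  tied_top <- vapply(split(srt$size_mm, srt$patient_id),
                     function(s) length(s) > 1 && sum(s == max(s)) > 1, logical(1))
  out <- srt[keep, , drop = FALSE]
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- attr(cohort, "params")
  attr(out, "ties") <- as.integer(names(tied_top)[tied_top])
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Apply eligibility exclusions with flow accounting
#'
#' Removes patients carrying any exclusion flag and returns the screening
#' flow: number sampled, excluded per reason, excluded total, included.
#' Always `sampled = excluded + included`.
#'
#' @param cohort a `cohort_table`.
#' @param flags data.frame with `patient_id` and one logical column per
#'   exclusion reason (e.g. non_saccular, thrombus, calcification,
#'   image_quality, opt_out).
#' @return List with `cohort` (included patients) and `flow`.
#' @export
apply_exclusions <- function(cohort, flags) {
  stopifnot(is.data.frame(flags), "patient_id" %in% names(flags))
  reasons <- setdiff(names(flags), "patient_id")
  if (!length(reasons)) stop("`flags` needs at least one reason column")
  any_flag <- Reduce(`|`, lapply(flags[reasons], as.logical))
  excluded_ids <- flags$patient_id[any_flag]
  out <- cohort[!(cohort$patient_id %in% excluded_ids), , drop = FALSE]
  n_sampled <- length(unique(cohort$patient_id))
  n_excl <- length(unique(excluded_ids))
  flow <- list(sampled = n_sampled,
               excluded_by_reason = vapply(flags[reasons],
                                           function(f) sum(as.logical(f)), integer(1)),
               excluded = n_excl,
               included = n_sampled - n_excl)
  if (flow$included == 0) warning("all patients excluded: empty cohort")
  attr(out, "params") <- attr(cohort, "params")
  class(out) <- c("cohort_table", "data.frame")
  list(cohort = out, flow = flow)
}
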