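#' Configuration of the sex-difference analysis
#'
#' @param adjustment confounder set for the multivariable models. `"size"`
#'   enters as log(size); the volume model never adjusts for size.
#' @param m,iterations,seed multiple-imputation settings.
#' @param conf_level confidence level for all intervals.
#' @param linear_outcomes outcomes analyzed with linear regression of the
#'   standardized value.
#' @param logistic_outcomes low-variability outcomes dichotomized at the
#'   median and analyzed with logistic regression (also analyzed as
#'   continuous exploratory linear models).
#' @param drop_smoking,complete_case sensitivity toggles used by
#'   [run_sensitivity()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(adjustment = c("age", "hypertension", "smoking",
                                           "size", "location", "modality"),
                            m = 15L, iterations = 30L, seed = 1L,
                            conf_level = 0.95,
                            linear_outcomes = c("volume", "sphericity",
                                                "elongation", "flatness"),
                            logistic_outcomes = c("shape_index", "curvedness"),
                            drop_smoking = FALSE, complete_case = FALSE) {
  structure(list(adjustment = adjustment, m = as.integer(m),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 conf_level = conf_level,
                 linear_outcomes = linear_outcomes,
                 logistic_outcomes = logistic_outcomes,
                 drop_smoking = drop_smoking, complete_case = complete_case),
            class = "analysis_config")
}

outcome_column <- function(oc) if (oc == "volume") "volume_mm3" else oc

validate_cohort_schema <- function(cohort) {
  need <- c("patient_id", "sex", "age", "hypertension", "smoking", "location",
            "modality", "size_mm", "volume_mm3", "sphericity", "elongation",
            "flatness", "shape_index", "curvedness")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort schema violation; missing columns: ", paste(missing, collapse = ", "))
  if (!all(c("man", "woman") %in% levels(factor(cohort$sex))) ||
      length(unique(cohort$sex)) < 2L)
    stop("both sexes must be present")
  morph <- c("volume_mm3", "sphericity", "elongation", "flatness",
             "shape_index", "curvedness", "size_mm", "age")
  bad <- morph[vapply(cohort[morph], anyNA, logical(1))]
  if (length(bad))
    stop("missing values only allowed in `smoking`; found NA in: ",
         paste(bad, collapse = ", "))
  invisible(cohort)
}

# collapse raw categories to the analysis coding
analysis_frame <- function(cohort) {
  loc <- as.character(cohort$location)
  loc[loc %in% c("PCom", "Posterior")] <- "PCom/Posterior"
  data.frame(
    sex = factor(cohort$sex, levels = c("man", "woman")),
    age = cohort$age,
    hypertension = cohort$hypertension,
    smoking = factor(cohort$smoking, levels = c("current", "former", "never")),
    location = factor(loc, levels = c("ACA/ACom", "ICA", "MCA", "PCom/Posterior")),
    modality = factor(cohort$modality, levels = c("MRA", "CTA")),
    size_log = log(cohort$size_mm))
}

med_iqr <- function(x, scale100 = FALSE) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (scale100) q <- 100 * q
  c(q25 = q[1], median = q[2], q75 = q[3])
}

#' Full women-vs-men morphology comparison on a cohort
#'
#' Implements the complete analysis: index-aneurysm selection, natural-log
#' transform of volume, Box-Cox transform of elongation (lambda estimated
#' once on the observed column), Z-standardization of all morphology
#' outcomes, median dichotomization of the local shape parameters, multiple
#' imputation of missing smoking status, per-imputation univariable and
#' multivariable regressions and Rubin's-rules pooling. Local shape
#' parameters are additionally analyzed as continuous outcomes (exploratory
#' linear models). The volume model is not adjusted for size.
#'
#' @param cohort a `cohort_table` (may contain multiple aneurysms per
#'   patient and missing smoking values).
#' @param config an [analysis_config()].
#' @return An object of class `results_table`: list with `table` (tidy
#'   data.frame, one row per outcome x analysis), `estimates` (the pooled
#'   `effect_estimate`s), `medians` (per-sex median/IQR, x100 display scale
#'   for the shape parameters) and `manifest` (seed, m, iterations, Box-Cox
#'   lambda, dichotomization medians, sample sizes).
#' @export
run_sex_comparison <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  validate_cohort_schema(cohort)
  if (anyDuplicated(cohort$patient_id)) cohort <- select_index_aneurysm(cohort)
  n <- nrow(cohort)
  af <- analysis_frame(cohort)

  # transformations + standardization moments from the (complete) observed columns
  bc <- boxcox_transform(cohort$elongation)
  trans <- list(
    volume = z_standardize(log_transform(cohort$volume_mm3)$values),
    sphericity = z_standardize(cohort$sphericity),
    elongation = z_standardize(bc$values),
    flatness = z_standardize(cohort$flatness),
    shape_index = z_standardize(cohort$shape_index),
    curvedness = z_standardize(cohort$curvedness))
  dich <- lapply(config$logistic_outcomes, function(oc)
    dichotomize_median(cohort[[outcome_column(oc)]]))
  names(dich) <- config$logistic_outcomes

  # imputation data: covariates + transformed outcomes
  imp_data <- af
  for (oc in names(trans)) imp_data[[paste0("z_", oc)]] <- trans[[oc]]$values
  imp <- impute_chained(imp_data, m = config$m, iterations = config$iterations,
                        seed = config$seed)

  adj_terms <- function(oc) {
    terms <- intersect(config$adjustment,
                       c("age", "hypertension", "smoking", "size", "location", "modality"))
    if (oc == "volume") terms <- setdiff(terms, "size")
    terms
  }
  design_for <- function(frame, terms) {
    d <- data.frame(sex = frame$sex)
    if ("age" %in% terms) d$age <- frame$age
    if ("hypertension" %in% terms) d$hypertension <- frame$hypertension
    if ("smoking" %in% terms)
      d$smoking_ever <- as.integer(frame$smoking != "never")
    if ("size" %in% terms) d$size_log <- frame$size_log
    if ("location" %in% terms) d$location <- frame$location
    if ("modality" %in% terms) d$modality <- frame$modality
    d
  }
  fit_pooled <- function(outcome, terms, engine) {
    ests <- lapply(imp$completed, function(frame)
      engine(outcome, design_for(frame, terms), conf_level = config$conf_level))
    pool_rubin(ests, conf_level = config$conf_level)
  }

  estimates <- list()
  rows <- list()
  add_row <- function(outcome, analysis, model, est) {
    key <- paste(outcome, model, analysis, sep = ".")
    estimates[[key]] <<- est
    on_or <- est$scale == "or"
    rows[[key]] <<- data.frame(
      outcome = outcome, analysis = analysis, model = model,
      scale = if (on_or) "OR" else "beta",
      estimate = if (on_or) exp(est$estimate) else est$estimate,
      ci_low = if (on_or) exp(est$ci[1]) else est$ci[1],
      ci_high = if (on_or) exp(est$ci[2]) else est$ci[2],
      se = est$se, df = est$df,
      adjustment = paste(est$adjustment, collapse = "+"))
  }

  for (oc in config$linear_outcomes) {
    y <- trans[[oc]]$values
    add_row(oc, "univariable", "linear", fit_pooled(y, character(0), fit_linear))
    add_row(oc, "multivariable", "linear", fit_pooled(y, adj_terms(oc), fit_linear))
  }
  for (oc in config$logistic_outcomes) {
    yb <- dich[[oc]]
    add_row(oc, "univariable", "logistic", fit_pooled(yb, character(0), fit_logistic))
    add_row(oc, "multivariable", "logistic", fit_pooled(yb, adj_terms(oc), fit_logistic))
    yz <- trans[[oc]]$values
    add_row(oc, "univariable", "linear-exploratory", fit_pooled(yz, character(0), fit_linear))
    add_row(oc, "multivariable", "linear-exploratory", fit_pooled(yz, adj_terms(oc), fit_linear))
  }

  # per-sex medians/IQR, display x100 for the shape parameters
  meds <- list()
  for (oc in c("volume", names(trans)[-1])) {
    col <- outcome_column(oc)
    x100 <- oc != "volume"
    meds[[oc]] <- rbind(
      total = med_iqr(cohort[[col]], x100),
      woman = med_iqr(cohort[[col]][cohort$sex == "woman"], x100),
      man = med_iqr(cohort[[col]][cohort$sex == "man"], x100))
  }

  manifest <- list(
    n = n,
    n_women = sum(cohort$sex == "woman"),
    n_men = sum(cohort$sex == "man"),
    n_missing_smoking = sum(is.na(cohort$smoking)),
    complete_case_n = sum(!is.na(cohort$smoking)),
    m = config$m, iterations = config$iterations, seed = config$seed,
    boxcox_lambda = bc$lambda,
    dichotomization_medians = vapply(dich, function(d) attr(d, "median"), numeric(1)),
    adjustment = config$adjustment)

  res <- structure(list(table = do.call(rbind, rows), estimates = estimates,
                        medians = meds, manifest = manifest),
                   class = "results_table")
  rownames(res$table) <- NULL
  annotate_direction(res)
}

#' @export
print.results_table <- function(x, ...) {
  cat(sprintf("<results_table> n=%d (%d women, %d men), m=%d imputations\n",
              x$manifest$n, x$manifest$n_women, x$manifest$n_men, x$manifest$m))
  print(x$table[, c("outcome", "analysis", "model", "scale", "estimate",
                    "ci_low", "ci_high", "direction")], digits = 3)
  invisible(x)
}

#' Label estimates by rupture-prone direction
#'
#' Pure function of the estimates and the instability coding: larger volume,
#' lower sphericity / elongation / flatness, lower shape index and higher
#' curvedness characterize rupture-prone aneurysms. A women-vs-men estimate
#' whose CI excludes the null is labelled "more rupture-prone in women" or
#' "less rupture-prone in women" accordingly; otherwise "no difference".
#'
#' @param results a `results_table` (or its `table` data.frame).
#' @return The input with a `direction` column added/updated.
#' @export
annotate_direction <- function(results) {
  tab <- if (inherits(results, "results_table")) results$table else results
  higher_is_prone <- c(volume = TRUE, sphericity = FALSE, elongation = FALSE,
                       flatness = FALSE, shape_index = FALSE, curvedness = TRUE)
  null_val <- ifelse(tab$scale == "OR", 1, 0)
  sig <- tab$ci_low > null_val | tab$ci_high < null_val
  women_higher <- tab$estimate > null_val
  prone <- women_higher == higher_is_prone[tab$outcome]
  tab$direction <- ifelse(!sig, "no difference",
                          ifelse(prone, "more rupture-prone in women",
                                 "less rupture-prone in women"))
  if (inherits(results, "results_table")) {
    results$table <- tab
    results
  } else tab
}

#' The two smoking sensitivity analyses
#'
#' Analysis 1 drops smoking from the adjustment set (full cohort); analysis
#' 2 keeps smoking but restricts to patients with observed smoking status
#' (complete cases; with no missing values it equals the main analysis
#' exactly).
#'
#' @param cohort a `cohort_table`.
#' @param config an [analysis_config()].
#' @return List with `drop_smoking` and `complete_case` `results_table`s.
#' @export
run_sensitivity <- function(cohort, config = analysis_config()) {
  cfg1 <- config
  cfg1$adjustment <- setdiff(config$adjustment, "smoking")
  cfg1$drop_smoking <- TRUE
  drop_smoking <- run_sex_comparison(cohort, cfg1)

  cc <- cohort[!is.na(cohort$smoking), , drop = FALSE]
  class(cc) <- class(cohort)
  attr(cc, "params") <- attr(cohort, "params")
  cfg2 <- config
  cfg2$complete_case <- TRUE
  complete_case <- run_sex_comparison(cc, cfg2)

  list(drop_smoking = drop_smoking, complete_case = complete_case)
}

#' Batch morphometry over a directory of NIfTI masks
#'
#' Each readable mask is preprocessed (largest 26-connected component, then
#' optional resampling to `target_spacing`) and quantified with
#' [summarize_morphology()]; one CSV row per mask. Unreadable or failing
#' files are logged and skipped — the batch continues.
#'
#' @param mask_dir directory containing `.nii` / `.nii.gz` masks.
#' @param target_spacing harmonization spacing in mm (`NULL` = keep native).
#' @param out_csv optional path to write the feature table.
#' @param ... passed to [summarize_morphology()].
#' @return A data.frame of features with attribute `failures` (named list of
#'   error messages).
#' @export
run_morphometry_batch <- function(mask_dir, target_spacing = NULL,
                                  out_csv = NULL, ...) {
  files <- sort(list.files(mask_dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
  if (!length(files)) stop("no NIfTI masks found in ", mask_dir)
  failures <- list()
  rows <- list()
  for (f in files) {
    id <- sub("\\.nii(\\.gz)?$", "", basename(f))
    res <- tryCatch({
      m <- read_nifti_mask(f)
      m <- largest_component(m)
      if (!is.null(target_spacing) &&
          any(abs(m$spacing - rep(target_spacing, length.out = 3)) > 1e-9))
        m <- resample_mask(m, target_spacing)
      cbind(id = id, as.data.frame(summarize_morphology(m, ...)))
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[id]] <- conditionMessage(res)
    else rows[[id]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  if (length(failures))
    message(length(failures), " mask(s) failed: ", paste(names(failures), collapse = ", "))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Write a results table (plus manifest) to disk
#'
#' @param results a `results_table`.
#' @param csv_path path for the tidy CSV.
#' @param manifest_path optional path for the JSON run manifest.
#' @export
write_results <- function(results, csv_path, manifest_path = NULL) {
  stopifnot(inherits(results, "results_table"))
  utils::write.csv(results$table, csv_path, row.names = FALSE)
  if (!is.null(manifest_path))
    jsonlite::write_json(results$manifest, manifest_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}
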