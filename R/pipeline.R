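# Pipeline orchestration: simulate, measure, analyze -----------------------

#' Full diagnostic-accuracy analysis of a fracture-outcome cohort
#'
#' Runs the complete statistical pipeline on a cohort table: per-group
#' descriptives, Welch t-tests on BMD and age, Fisher's exact test on the
#' sex distribution, the empirical ROC of BMD against the 2-year fracture
#' outcome with Youden-optimal cut-off and AUC CI, diagnostic metrics
#' (exact binomial CIs) at the optimal and at any fixed configured
#' cut-off, ACR band tabulation, and the multivariable logistic model in
#' BMD, age and sex.
#'
#' @param cohort Cohort data frame (schema of [generate_cohort()]).
#' @param fixed_cutoff Optional additional decision threshold (mg/cm3).
#' @param ci_level Confidence level used throughout (default 0.95).
#' @param acr_low,acr_high ACR band edges (default 80 and 120 mg/cm3).
#' @return A list of class `cohort_analysis` with elements `descriptives`,
#'   `tests`, `roc`, `optimal_cutoff`, `metrics_optimal`, `metrics_fixed`
#'   (or NULL), `acr_bands`, `logistic`.
#' @export
analyze_cohort <- function(cohort, fixed_cutoff = NULL, ci_level = 0.95,
                           acr_low = 80, acr_high = 120) {
  cohort <- validate_cohort(cohort)
  if (length(unique(cohort$fracture_2y)) < 2) {
    stop_dect("degenerate labels: cohort must contain both outcome groups",
              "dectbmd_degenerate_labels")
  }
  frac <- cohort[cohort$fracture_2y == 1, ]
  ctrl <- cohort[cohort$fracture_2y == 0, ]
  grp <- function(x) c(n = length(x), mean = mean(x), sd = stats::sd(x),
                       min = min(x), max = max(x))
  descriptives <- list(
    n_total = nrow(cohort), n_fracture = nrow(frac), n_control = nrow(ctrl),
    bmd_fracture = grp(frac$bmd_mg_cm3), bmd_control = grp(ctrl$bmd_mg_cm3),
    bmd_overall = grp(cohort$bmd_mg_cm3),
    age_fracture = grp(frac$age_years), age_control = grp(ctrl$age_years),
    days_to_fracture = if (nrow(frac)) grp(frac$days_to_fracture) else NULL)
  sex_tab <- table(factor(cohort$sex, levels = c("male", "female")),
                   factor(cohort$fracture_2y, levels = c(0, 1)))
  tests <- list(
    bmd_t = unpaired_t_test(frac$bmd_mg_cm3, ctrl$bmd_mg_cm3),
    age_t = unpaired_t_test(frac$age_years, ctrl$age_years),
    sex_fisher_p = fishers_exact_2x2(sex_tab))
  roc <- empirical_roc(cohort$bmd_mg_cm3, cohort$fracture_2y,
                       direction = "lower_positive", ci_level = ci_level)
  opt <- youden_optimal_cutoff(roc)
  m_opt <- diagnostic_metrics(
    apply_cutoff(cohort$bmd_mg_cm3, opt$threshold, cohort$fracture_2y)$counts,
    ci_level)
  m_fix <- if (!is.null(fixed_cutoff)) {
    diagnostic_metrics(
      apply_cutoff(cohort$bmd_mg_cm3, fixed_cutoff, cohort$fracture_2y)$counts,
      ci_level)
  }
  bands <- classify_acr(cohort$bmd_mg_cm3)
  acr_bands <- table(band = bands, fracture = cohort$fracture_2y)
  logit <- fit_logistic(cohort$fracture_2y,
                        data.frame(bmd = cohort$bmd_mg_cm3,
                                   age = cohort$age_years,
                                   female = as.integer(cohort$sex == "female")),
                        ci_level = ci_level)
  structure(list(descriptives = descriptives, tests = tests, roc = roc,
                 optimal_cutoff = opt, metrics_optimal = m_opt,
                 metrics_fixed = m_fix, acr_bands = acr_bands,
                 logistic = logit),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("Cohort: %d patients (%d fracture / %d control)\n",
              d$n_total, d$n_fracture, d$n_control))
  cat(sprintf("BMD mg/cm3: fracture %.1f +/- %.1f, control %.1f +/- %.1f (t-test p = %.3g)\n",
              d$bmd_fracture[["mean"]], d$bmd_fracture[["sd"]],
              d$bmd_control[["mean"]], d$bmd_control[["sd"]], x$tests$bmd_t$p))
  cat(sprintf("ROC AUC = %.3f (%.0f%% CI %.3f-%.3f)\n", x$roc$auc,
              100 * x$roc$auc_ci$level, x$roc$auc_ci$lo, x$roc$auc_ci$hi))
  o <- x$optimal_cutoff
  cat(sprintf("Youden cut-off %.2f mg/cm3 (J = %.3f): sens %.1f%%, spec %.1f%%\n",
              o$threshold, o$j, 100 * o$sensitivity, 100 * o$specificity))
  cat(sprintf("Logistic: OR(BMD) = %.4f, OR(age) = %.4f, Nagelkerke R2 = %.3f\n",
              x$logistic$coefficients$or[2], x$logistic$coefficients$or[3],
              x$logistic$nagelkerke_r2))
  invisible(x)
}

roc_curve_df <- function(roc) {
  data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
             specificity = roc$specificity)
}

manifest_for <- function(inputs, seed, config) {
  list(package = "dectbmd",
       version = as.character(utils::packageVersion("dectbmd")),
       seed = seed,
       inputs = lapply(inputs, function(p) {
         if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
       }),
       config = config)
}

#' Simulate a dual-energy phantom to disk
#'
#' Writes the low/high-energy NIfTI pair, the true trabecular mask, the
#' truth record (YAML) and a run manifest into `out_dir`. Bit-identical
#' re-runs for a fixed spec (including its seed).
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @param c Calibration constants (default packaged).
#' @return Invisibly, the named list of written paths.
#' @export
run_simulate_phantom <- function(spec, out_dir, c = default_constants()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- generate_phantom(spec, c)
  paths <- list(lo = file.path(out_dir, "phantom_90kvp.nii.gz"),
                hi = file.path(out_dir, "phantom_sn150kvp.nii.gz"),
                mask = file.path(out_dir, "phantom_voi.nii.gz"),
                truth = file.path(out_dir, "phantom_truth.yaml"),
                manifest = file.path(out_dir, "manifest.json"))
  write_volume_nifti(ph$volumes$lo, spec$grid, paths$lo)
  write_volume_nifti(ph$volumes$hi, spec$grid, paths$hi)
  write_mask_nifti(ph$mask, paths$mask)
  yaml::write_yaml(ph$truth, paths$truth)
  jsonlite::write_json(
    manifest_for(list(), spec$seed,
                 list(stage = "simulate-phantom",
                      dims = spec$grid$dims, noise_sd = spec$noise_sd,
                      v_tb = spec$v_tb, v_f = spec$v_f)),
    paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Measure ROI BMD from volume and mask files
#'
#' Reads the co-registered NIfTI pair and VOI mask, runs the canonical
#' ROI-mean decomposition, and returns the measurement with its ACR band.
#'
#' @param lo_path,hi_path NIfTI paths of the two energy volumes.
#' @param mask_path NIfTI path of the VOI mask.
#' @param c Calibration constants.
#' @return List with `measurement` (a `bmd_measurement`) and `acr_band`.
#' @export
run_measure <- function(lo_path, hi_path, mask_path, c = default_constants()) {
  lo <- read_volume_nifti(lo_path)
  hi <- read_volume_nifti(hi_path)
  mask <- read_mask_nifti(mask_path)
  check_same_grid(lo$grid, hi$grid)
  vols <- dect_volume_pair(lo$data, hi$data, lo$grid)
  m <- roi_bmd(vols, mask, c)
  list(measurement = m, acr_band = as.character(classify_acr(m$bmd_mg_cm3)))
}

#' Simulate a cohort CSV to disk
#'
#' @param params A [cohort_params()].
#' @param path Output CSV path.
#' @return The cohort data frame, invisibly.
#' @export
run_simulate_cohort <- function(params, path) {
  cohort <- generate_cohort(params)
  write_cohort_csv(cohort, path)
  invisible(cohort)
}

#' Analyze a cohort CSV and write the report bundle
#'
#' Runs [analyze_cohort()] and writes `report.yaml` (every fitted
#' quantity: descriptives, test p-values, AUC with CI, optimal cut-off,
#' diagnostic metrics, ACR band counts, logistic coefficients/ORs/R2),
#' `roc_curve.csv` (threshold, sensitivity, specificity) and
#' `manifest.json` into `out_dir`.
#'
#' @param cohort_csv Input cohort CSV path.
#' @param out_dir Output directory.
#' @inheritParams analyze_cohort
#' @return The `cohort_analysis` object, invisibly.
#' @export
run_analyze <- function(cohort_csv, out_dir, fixed_cutoff = NULL,
                        ci_level = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort_csv(cohort_csv)
  an <- analyze_cohort(cohort, fixed_cutoff = fixed_cutoff,
                       ci_level = ci_level)
  report <- list(
    n = an$descriptives[c("n_total", "n_fracture", "n_control")],
    bmd = list(fracture = as.list(an$descriptives$bmd_fracture),
               control = as.list(an$descriptives$bmd_control),
               overall = as.list(an$descriptives$bmd_overall)),
    age = list(fracture = as.list(an$descriptives$age_fracture),
               control = as.list(an$descriptives$age_control)),
    tests = list(bmd_t_p = an$tests$bmd_t$p, age_t_p = an$tests$age_t$p,
                 sex_fisher_p = an$tests$sex_fisher_p),
    roc = list(auc = an$roc$auc, ci = an$roc$auc_ci),
    optimal_cutoff = an$optimal_cutoff,
    metrics_optimal = an$metrics_optimal,
    metrics_fixed = an$metrics_fixed,
    acr_bands = as.list(stats::setNames(as.vector(an$acr_bands),
                                        outer(rownames(an$acr_bands),
                                              c("control", "fracture"),
                                              paste, sep = "_"))),
    logistic = list(coefficients = an$logistic$coefficients,
                    lr_chisq = an$logistic$lr_chisq,
                    lr_p = an$logistic$lr_p,
                    nagelkerke_r2 = an$logistic$nagelkerke_r2,
                    model_auc = an$logistic$model_auc))
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  utils::write.csv(roc_curve_df(an$roc), file.path(out_dir, "roc_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    manifest_for(list(cohort = cohort_csv), NA,
                 list(stage = "analyze", fixed_cutoff = fixed_cutoff,
                      ci_level = ci_level)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(an)
}
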