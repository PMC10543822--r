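# End-to-end pipeline: inclusion filters -> scoring -> recalibration -> the
# full analysis battery, returning one structured report.

# Table-2-style adjuster order for the sequential ladder
default_adjuster_order <- function() {
  c("age_years", "elective_surgery", "chronic_respiratory",
    "chronic_cardiovascular", "cirrhosis", "esrf", "immune_disease",
    "immunosuppressed", "aids", "lymphoma", "metastatic_cancer", "leukemia",
    "diabetes")
}

#' Run the full biological-age mortality analysis
#'
#' Executes the pipeline on a supplied cohort table or on a freshly simulated
#' one: readmission exclusion, phenotypic-age scoring, within-cohort
#' recalibration, descriptive group comparison, AUROC discrimination of the
#' age measures with a DeLong comparison against chronological age, the
#' sequential Cox adjustment ladder with a final full model (including the
#' APACHE II > 15 indicator), Kaplan-Meier and mean-covariate adjusted
#' survival contrasts for the acceleration flag, the 4-knot spline
#' dose-response curve of the residual, the comorbidity odds-ratio table,
#' and the Hanley-McNeil power block.
#'
#' @param cohort A cohort data.frame (see
#'   \code{\link{cohort_required_columns}}); \code{NULL} to simulate.
#' @param config A \code{\link{simulation_config}} used when \code{cohort}
#'   is \code{NULL}.
#' @param coeffs A \code{\link{phenoage_coefficients}} object.
#' @param crp_floor CRP clamp floor, mg/dL.
#' @param apache_cut Severity dichotomization threshold for the final model
#'   (indicator is \code{apache_ii > apache_cut}). Default 15.
#' @param adjusters Ladder adjuster order.
#' @param p_entry Optional significance-gated forward entry threshold for
#'   the ladder (see \code{\link{sequential_cox}}).
#' @return Object of class \code{analysis_report}; a list with elements
#'   \code{log}, \code{recalibration}, \code{table_one}, \code{roc},
#'   \code{roc_comparison}, \code{ladder}, \code{final_model},
#'   \code{concordance}, \code{survival_curves}, \code{spline},
#'   \code{comorbidity_or}, \code{power}, \code{cohort} (the augmented
#'   table).
#' @examples
#' \donttest{
#' rep <- run_pipeline(config = simulation_config(n = 600, seed = 11))
#' rep$ladder$ladder
#' }
#' @export
run_pipeline <- function(cohort = NULL, config = NULL,
                         coeffs = phenoage_coefficients(),
                         crp_floor = 0.01, apache_cut = 15,
                         adjusters = default_adjuster_order(),
                         p_entry = NULL) {
  if (is.null(cohort)) {
    if (is.null(config)) config <- simulation_config()
    cohort <- generate_cohort(config)
  }
  truth <- attr(cohort, "truth")
  n_input <- nrow(cohort)
  cohort <- exclude_readmissions(cohort)
  n_readmit <- attr(cohort, "n_readmissions_excluded")

  cohort <- add_phenoage_measures(cohort, coeffs, crp_floor = crp_floor)
  recal <- attr(cohort, "recalibration")
  cohort$apache_gt15 <- as.integer(cohort$apache_ii > apache_cut)

  tab1 <- table_one(cohort,
                    continuous = c("age_years", "phenoage_years",
                                   "age_gap_years", "apache_ii",
                                   "time_days"),
                    categorical = c("phenoage_accel", "elective_surgery",
                                    comorbidity_names(), "apache_gt15"))

  ev <- cohort$died_in_hospital
  measures <- c(chronological_age = "age_years",
                phenoage = "phenoage_years",
                age_gap = "age_gap_years",
                accel_residual = "accel_residual_years",
                phenoage_accel = "phenoage_accel")
  roc <- lapply(measures, function(cl) auroc(cohort[[cl]], ev))
  roc_tab <- data.frame(measure = names(measures),
                        auc = vapply(roc, `[[`, numeric(1), "auc"),
                        ci_low = vapply(roc, `[[`, numeric(1), "ci_low"),
                        ci_high = vapply(roc, `[[`, numeric(1), "ci_high"))
  rownames(roc_tab) <- NULL
  roc_cmp <- compare_auroc(cohort$phenoage_years, cohort$age_years, ev)

  ladder <- sequential_cox(cohort, focal = "phenoage_accel",
                           ordered_adjusters = adjusters,
                           final_extra = "apache_gt15", p_entry = p_entry)

  curves <- survival_contrast(cohort, ladder$final_fit)

  spline <- spline_hazard_curve(cohort$time_days, ev,
                                cohort$accel_residual_years)

  orr <- comorbidity_odds(cohort)

  power <- list(auc_060 = auroc_sample_size(0.60),
                auc_065 = auroc_sample_size(0.65))

  log <- list(package_version = as.character(utils::packageVersion("phenoage")),
              coefficients = coeffs$name,
              coefficients_md5 = attr(coeffs, "checksum"),
              seed = truth$seed,
              n_input = n_input,
              n_readmissions_excluded = n_readmit,
              n_analyzed = nrow(cohort),
              n_events = sum(ev))

  structure(list(log = log,
                 recalibration = recal,
                 table_one = tab1,
                 roc = roc_tab,
                 roc_comparison = roc_cmp,
                 ladder = ladder,
                 final_model = ladder$final,
                 concordance = ladder$final_fit$concordance,
                 survival_curves = curves,
                 spline = spline,
                 comorbidity_or = orr,
                 power = power,
                 cohort = cohort),
            class = "analysis_report")
}

# Kaplan-Meier curves by acceleration flag with log-rank p, and adjusted
# curves from the final Cox model by the mean-covariate method (every other
# covariate held at its cohort mean)
survival_contrast <- function(cohort, final_fit) {
  sf <- survival::survfit(
    survival::Surv(time_days, died_in_hospital) ~ phenoage_accel,
    data = cohort)
  km <- data.frame(time = sf$time,
                   surv = sf$surv,
                   group = rep(sub("phenoage_accel=", "",
                                   names(sf$strata)), sf$strata))
  lr <- survival::survdiff(
    survival::Surv(time_days, died_in_hospital) ~ phenoage_accel,
    data = cohort)
  logrank_p <- pchisq(lr$chisq, df = 1, lower.tail = FALSE)

  adjusted <- NULL
  if (!is.null(final_fit$fit)) {
    terms <- final_fit$coefficients$term
    nd <- as.data.frame(lapply(cohort[, terms, drop = FALSE], mean))
    nd <- nd[c(1, 1), , drop = FALSE]
    nd$phenoage_accel <- c(0, 1)
    sfa <- survival::survfit(final_fit$fit, newdata = nd)
    adjusted <- data.frame(time = rep(sfa$time, 2),
                           surv = c(sfa$surv[, 1], sfa$surv[, 2]),
                           group = rep(c("0", "1"), each = length(sfa$time)))
  }
  list(km = km, logrank_p = logrank_p, adjusted = adjusted)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Biological-age mortality analysis report\n")
  cat(sprintf("  analyzed %d patients (%d readmissions excluded), %d deaths (%.1f%%)\n",
              x$log$n_analyzed, x$log$n_readmissions_excluded,
              x$log$n_events, 100 * x$log$n_events / x$log$n_analyzed))
  cat(sprintf("  recalibration: PhenoAge = %.1f + %.3f * age; accelerated %.1f%%\n",
              x$recalibration$intercept, x$recalibration$slope,
              100 * mean(x$recalibration$accel_flag)))
  cat("  AUROC:\n")
  print(transform(x$roc, auc = round(auc, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3)), row.names = FALSE)
  cat(sprintf("  DeLong phenoage vs chronological age: dAUC = %.3f, p = %.3g\n",
              x$roc_comparison$difference, x$roc_comparison$p_value))
  f <- x$ladder$ladder
  cat(sprintf("  focal HR: univariable %.3f -> fully adjusted %.3f; final-model C = %.3f\n",
              f$hr[1],
              x$final_model$hr[x$final_model$term == "phenoage_accel"],
              x$concordance))
  cat(sprintf("  spline nonlinearity p = %.3g; log-rank p = %.3g\n",
              x$spline$p_nonlinear, x$survival_curves$logrank_p))
  cat(sprintf("  power: n = %d for AUC 0.60, n = %d for AUC 0.65\n",
              x$power$auc_060$n_total, x$power$auc_065$n_total))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits \code{report.json} (structured results), \code{tables.txt} (plain
#' text rendering of the descriptive, ladder and odds-ratio tables) and
#' \code{spline_curve.csv} / \code{survival_curves.csv} (x, estimate, bounds
#' grids suitable for any plotting layer) into a directory.
#'
#' @param report An \code{analysis_report}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    log = report$log,
    recalibration = list(slope = report$recalibration$slope,
                         intercept = report$recalibration$intercept,
                         n = report$recalibration$n,
                         accel_prevalence =
                           mean(report$recalibration$accel_flag)),
    table_one = report$table_one,
    roc = report$roc,
    roc_comparison = report$roc_comparison,
    ladder = report$ladder$ladder,
    final_model = report$final_model,
    concordance = report$concordance,
    logrank_p = report$survival_curves$logrank_p,
    spline = list(knots = report$spline$knots,
                  p_nonlinear = report$spline$p_nonlinear),
    comorbidity_or = report$comorbidity_or,
    power = report$power)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$spline$curve, file.path(dir, "spline_curve.csv"),
                   row.names = FALSE)
  km <- report$survival_curves$km
  km$curve <- "kaplan_meier"
  out_curves <- km
  if (!is.null(report$survival_curves$adjusted)) {
    adj <- report$survival_curves$adjusted
    adj$curve <- "adjusted_mean_covariate"
    out_curves <- rbind(km, adj)
  }
  utils::write.csv(out_curves, file.path(dir, "survival_curves.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "tables.txt"), "w")
  sink(con)
  on.exit({ sink(); close(con) })
  print(report)
  cat("\n== Descriptive comparison (survivors vs non-survivors) ==\n")
  print(report$table_one, row.names = FALSE)
  cat("\n== Sequential Cox ladder ==\n")
  print(report$ladder)
  cat("\n== Comorbidity odds ratios for the acceleration flag ==\n")
  print(report$comorbidity_or, row.names = FALSE)
  invisible(dir)
}
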