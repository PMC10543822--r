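# Coefficient handling: the scoring weights live in a versioned JSON file so
# the exact published constants can be swapped without touching code.

#' Names of the nine biomarkers, in canonical scoring order
#'
#' Canonical units: albumin g/L, creatinine umol/L, glucose mmol/L,
#' CRP mg/dL (entering the model as its natural log), lymphocyte percentage of
#' white cells, MCV fL, RDW %, alkaline phosphatase U/L, white cell count
#' 10^9/L.
#'
#' @return Character vector of length 9.
#' @export
biomarker_names <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymphocyte_pct",
    "mcv", "rdw", "alp", "wbc")
}

# CSV column name for each biomarker (canonical-unit dialect)
panel_columns <- function() {
  c(albumin = "albumin_g_l", creatinine = "creatinine_umol_l",
    glucose = "glucose_mmol_l", crp = "crp_mg_dl",
    lymphocyte_pct = "lymphocyte_pct", mcv = "mcv_fl", rdw = "rdw_pct",
    alp = "alp_u_l", wbc = "wbc_10e9_l")
}

#' Load phenotypic-age model coefficients
#'
#' Reads the weighted-linear-predictor coefficients, the Gompertz
#' mortality-score parameters and the age-scale inversion constants from a
#' flat JSON file. The shipped default, \code{phenoage_levine_default}, holds
#' the published Levine PhenoAge constants in the canonical units of
#' \code{\link{biomarker_names}}.
#'
#' @param path Path to a coefficient JSON file. \code{NULL} (default) loads
#'   the packaged default set.
#' @return An object of class \code{phenoage_coefficients}: a named list with
#'   \code{intercept}, one weight per biomarker (the CRP weight applies to
#'   \code{log(crp)}), \code{age}, \code{gompertz_gamma} (per month),
#'   \code{horizon_months}, and the inversion constants \code{inv_a},
#'   \code{inv_b}, \code{inv_c}. Carries attributes \code{path} and
#'   \code{checksum} (MD5 of the source file) for provenance logging.
#' @examples
#' cf <- phenoage_coefficients()
#' cf$age  # log-hazard increment per year of chronological age
#' @export
phenoage_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phenoage_levine_default.json",
                        package = "phenoage", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("coefficient file not found: ", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("intercept", "albumin", "creatinine", "glucose", "log_crp",
                "lymphocyte_pct", "mcv", "rdw", "alp", "wbc", "age",
                "gompertz_gamma", "horizon_months", "inv_a", "inv_b", "inv_c")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("coefficient file is missing keys: ", paste(missing, collapse = ", "))
  }
  cf <- lapply(raw[required], as.numeric)
  cf$name <- if (!is.null(raw$name)) as.character(raw$name) else basename(path)
  if (!all(vapply(cf[required], is.finite, logical(1)))) {
    stop("all coefficients must be finite numbers")
  }
  if (cf$gompertz_gamma <= 0) stop("gompertz_gamma must be positive")
  if (cf$horizon_months <= 0) stop("horizon_months must be positive")
  if (cf$inv_b <= 0) stop("inv_b must be positive")
  if (cf$inv_a >= 0) stop("inv_a must be negative")
  structure(cf,
            class = "phenoage_coefficients",
            path = path,
            checksum = unname(tools::md5sum(path)))
}

#' @export
print.phenoage_coefficients <- function(x, ...) {
  cat("Phenotypic-age coefficient set:", x$name, "\n")
  cat("  intercept:", format(x$intercept), "  age weight:", format(x$age),
      "/yr\n")
  w <- unlist(x[c("albumin", "creatinine", "glucose", "log_crp",
                  "lymphocyte_pct", "mcv", "rdw", "alp", "wbc")])
  cat("  biomarker weights:\n")
  print(w)
  cat("  Gompertz gamma:", format(x$gompertz_gamma), "/month over",
      x$horizon_months, "months\n")
  cat("  source:", attr(x, "path"), "\n")
  cat("  md5:", attr(x, "checksum"), "\n")
  invisible(x)
}
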