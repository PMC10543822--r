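# Cohort and labs file I/O, inclusion filters. CSV dialect throughout:
# comma-separated, UTF-8, header row, period decimal separator.

#' Required columns of a cohort CSV
#' @return Character vector of the required column names.
#' @export
cohort_required_columns <- function() {
  c("patient_id", "hosp_id", "admission_order", "age_years",
    unname(panel_columns()), comorbidity_names(),
    "elective_surgery", "apache_ii", "died_in_hospital", "time_days")
}

# accepted unit codes per analyte in the long labs format, with the
# multiplicative factor onto canonical units
lab_units <- function() {
  list(albumin = c(g_l = 1),
       creatinine = c(umol_l = 1),
       glucose = c(mmol_l = 1, mg_dl = 1 / 18.016),
       crp = c(mg_dl = 1, mg_l = 0.1),
       lymphocyte_pct = c(pct = 1),
       mcv = c(fl = 1),
       rdw = c(pct = 1),
       alp = c(u_l = 1),
       wbc = c("10e9_l" = 1, "10e3_ul" = 1))
}

#' Read a cohort CSV with schema validation
#'
#' Validates presence of every required column, then per-row sanity: finite
#' age in [0, 130], positive follow-up time, 0/1 flags, non-negative integer
#' severity score, finite biomarker values. Errors are aggregated and
#' reported with row numbers.
#'
#' @param path CSV file path.
#' @param permissive If \code{TRUE}, malformed rows are dropped with one
#'   warning listing them; if \code{FALSE} (default) any malformed row is an
#'   error.
#' @return Validated cohort data.frame (class \code{cohort_table}).
#' @export
read_cohort <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_required_columns(), names(cohort))
  if (length(missing) > 0) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  flags <- c(comorbidity_names(), "elective_surgery", "died_in_hospital")
  problems <- rep("", nrow(cohort))
  note <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    problems[bad] <<- paste(problems[bad], msg, sep = ";")
  }
  note(!is.finite(cohort$age_years) | cohort$age_years < 0 |
         cohort$age_years > 130, "age_years out of range")
  note(!is.finite(cohort$time_days) | cohort$time_days <= 0,
       "time_days not positive")
  note(!is.finite(cohort$apache_ii) | cohort$apache_ii < 0,
       "apache_ii negative")
  for (fl in flags) note(!cohort[[fl]] %in% c(0, 1), paste(fl, "not 0/1"))
  for (cl in unname(panel_columns())) {
    note(!is.finite(cohort[[cl]]), paste(cl, "not finite"))
  }
  bad <- which(nzchar(problems))
  if (length(bad) > 0) {
    msgs <- sprintf("row %d: %s", bad, sub("^;", "", problems[bad]))
    if (!permissive) {
      stop("malformed cohort rows:\n", paste(utils::head(msgs, 10),
                                             collapse = "\n"))
    }
    warning(length(bad), " malformed row(s) dropped: ",
            paste(utils::head(msgs, 10), collapse = "; "))
    cohort <- cohort[-bad, , drop = FALSE]
    rownames(cohort) <- NULL
  }
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Write a cohort CSV deterministically
#'
#' Stable column order (required columns first, extras after, both in fixed
#' order) and plain decimal formatting, so repeated writes of the same table
#' are byte-identical.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  lead <- intersect(cohort_required_columns(), names(cohort))
  rest <- setdiff(names(cohort), lead)
  utils::write.csv(cohort[, c(lead, rest)], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a long-format labs CSV
#'
#' Expected columns: \code{patient_id, hosp_id, analyte, value, unit,
#' time_h} (hours from ICU admission). Analyte names must come from the
#' closed nine-name vocabulary of \code{\link{biomarker_names}}; units from
#' the accepted dialect codes.
#'
#' @param path CSV file path.
#' @return Validated labs data.frame.
#' @export
read_labs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  labs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "hosp_id", "analyte", "value", "unit", "time_h")
  missing <- setdiff(need, names(labs))
  if (length(missing) > 0) {
    stop("labs file is missing column(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(unique(labs$analyte), biomarker_names())
  if (length(unknown) > 0) {
    stop("unknown analyte name(s): ", paste(unknown, collapse = ", "))
  }
  units <- lab_units()
  for (a in unique(labs$analyte)) {
    bad <- setdiff(unique(labs$unit[labs$analyte == a]), names(units[[a]]))
    if (length(bad) > 0) {
      stop("unresolvable unit(s) for ", a, ": ", paste(bad, collapse = ", "))
    }
  }
  if (any(!is.finite(labs$time_h))) stop("sample times must be finite")
  labs
}

#' Select each patient's admission biomarker panel from long-format labs
#'
#' Keeps results drawn within the admission window (default 0 to 24 hours
#' after ICU admission; pre-admission draws are excluded), converts values to
#' canonical units, and for each analyte repeated within the window uses the
#' one closest to the admission time. A patient is included only when all
#' nine analytes are present.
#'
#' @param labs Labs data.frame from \code{\link{read_labs}}.
#' @param window Inclusive time window in hours from admission.
#' @return List with \code{panels} (wide data.frame: \code{patient_id},
#'   canonical panel columns, one row per included patient) and
#'   \code{inclusion} (\code{patient_id, included, reason} for every input
#'   patient; the reason lists missing analytes).
#' @export
select_admission_panel <- function(labs, window = c(0, 24)) {
  units <- lab_units()
  all_ids <- unique(labs$patient_id)
  inwin <- labs[labs$time_h >= window[1] & labs$time_h <= window[2], ,
                drop = FALSE]
  # canonical units, then earliest draw per patient x analyte
  factor_for <- function(a, u) unname(units[[a]][u])
  inwin$value <- inwin$value *
    mapply(factor_for, inwin$analyte, inwin$unit)
  inwin <- inwin[order(inwin$patient_id, inwin$analyte, inwin$time_h), ,
                 drop = FALSE]
  first <- !duplicated(inwin[, c("patient_id", "analyte")])
  sel <- inwin[first, , drop = FALSE]

  panels <- NULL
  reasons <- character(length(all_ids))
  included <- logical(length(all_ids))
  for (i in seq_along(all_ids)) {
    pid <- all_ids[i]
    rows <- sel[sel$patient_id == pid, , drop = FALSE]
    missing <- setdiff(biomarker_names(), rows$analyte)
    if (length(missing) > 0) {
      reasons[i] <- paste("missing:", paste(missing, collapse = ","))
      next
    }
    included[i] <- TRUE
    vals <- setNames(rows$value, rows$analyte)[biomarker_names()]
    wide <- as.data.frame(as.list(vals))
    names(wide) <- unname(panel_columns()[biomarker_names()])
    panels <- rbind(panels, cbind(data.frame(patient_id = pid), wide))
  }
  list(panels = panels,
       inclusion = data.frame(patient_id = all_ids, included = included,
                              reason = reasons))
}

#' Keep only the first ICU admission per hospitalization
#'
#' @param cohort Cohort data.frame with \code{hosp_id} and
#'   \code{admission_order}.
#' @return The cohort restricted to each hospitalization's lowest admission
#'   order; the number of excluded readmissions is attached as attribute
#'   \code{n_readmissions_excluded}.
#' @export
exclude_readmissions <- function(cohort) {
  if (!all(c("hosp_id", "admission_order") %in% names(cohort))) {
    stop("cohort must carry hosp_id and admission_order")
  }
  key <- paste(cohort$hosp_id, cohort$admission_order)
  if (anyDuplicated(key) > 0) {
    stop("duplicate (hosp_id, admission_order) pairs")
  }
  first <- stats::ave(cohort$admission_order, cohort$hosp_id,
                      FUN = min) == cohort$admission_order
  out <- cohort[first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_readmissions_excluded") <- sum(!first)
  out
}
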