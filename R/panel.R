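# Biomarker panel validation and unit-dialect handling. The scoring weights
# are unit-specific, so silent unit mismatch is the dominant failure mode;
# everything is resolved to canonical units before any scoring happens.

# physiologic sanity ranges per analyte (canonical units); values outside
# these are almost certainly unit errors or data corruption, not biology
panel_ranges <- function() {
  list(albumin        = c(1, 80),      # g/L
       creatinine     = c(5, 4000),    # umol/L
       glucose        = c(0.2, 100),   # mmol/L
       crp            = c(0, 100),     # mg/dL; zero allowed before clamping
       lymphocyte_pct = c(0, 100),     # (0, 100]; zero rejected below
       mcv            = c(40, 160),    # fL
       rdw            = c(5, 45),      # %
       alp            = c(1, 5000),    # U/L
       wbc            = c(0.01, 500))  # 10^9/L
}

#' Construct a biomarker panel table
#'
#' Assembles per-patient biomarker values into the canonical panel layout used
#' by the scoring functions. All arguments are recycled to a common length.
#'
#' @param albumin Serum albumin, g/L.
#' @param creatinine Serum creatinine, umol/L.
#' @param glucose Glucose, mmol/L.
#' @param crp C-reactive protein, mg/dL (note: mg/dL, not mg/L).
#' @param lymphocyte_pct Lymphocytes as a percentage of white cells.
#' @param mcv Mean red-cell volume, fL.
#' @param rdw Red-cell distribution width, %.
#' @param alp Alkaline phosphatase, U/L.
#' @param wbc White cell count, 10^9 cells/L.
#' @return A data.frame with one column per biomarker, in canonical units.
#' @examples
#' biomarker_panel(albumin = 40, creatinine = 80, glucose = 5, crp = 0.1,
#'                 lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70, wbc = 7)
#' @export
biomarker_panel <- function(albumin, creatinine, glucose, crp, lymphocyte_pct,
                            mcv, rdw, alp, wbc) {
  data.frame(albumin = albumin, creatinine = creatinine, glucose = glucose,
             crp = crp, lymphocyte_pct = lymphocyte_pct, mcv = mcv,
             rdw = rdw, alp = alp, wbc = wbc)
}

#' Validate a biomarker panel and clamp CRP away from zero
#'
#' Checks every analyte against finiteness, positivity and physiologic range
#' limits, then replaces CRP values below the floor with the floor so that
#' \code{log(crp)} is always defined. A CRP of exactly zero (below the assay
#' detection limit) is legal input; it is clamped.
#'
#' @param panel A data.frame as returned by \code{\link{biomarker_panel}}, or
#'   any data.frame containing those nine columns.
#' @param crp_floor Detection floor for CRP in mg/dL; values below it
#'   (including 0) are raised to it. Default 0.01.
#' @return The panel with CRP clamped; stops with an error naming the analyte
#'   and offending rows otherwise.
#' @export
validate_panel <- function(panel, crp_floor = 0.01) {
  stopifnot(is.data.frame(panel))
  need <- biomarker_names()
  missing <- setdiff(need, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing analytes: ", paste(missing, collapse = ", "))
  }
  ranges <- panel_ranges()
  for (a in need) {
    v <- panel[[a]]
    if (!is.numeric(v)) stop("analyte ", a, " is not numeric")
    bad <- !is.finite(v)
    lo <- ranges[[a]][1]; hi <- ranges[[a]][2]
    bad <- bad | v < lo | v > hi
    if (a != "crp") bad <- bad | v <= 0
    if (any(bad)) {
      stop("invalid value(s) for ", a, " at row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           " (allowed range ", lo, "-", hi, ")")
    }
  }
  panel$crp <- pmax(panel$crp, crp_floor)
  panel
}

#' Convert a panel from common lab unit dialects to canonical units
#'
#' The scoring coefficients assume albumin g/L, creatinine umol/L, glucose
#' mmol/L, CRP mg/dL and WBC 10^9/L. Many laboratories report CRP in mg/L and
#' glucose in mg/dL; this converter resolves those dialects explicitly rather
#' than guessing from magnitudes.
#'
#' @param panel Panel data.frame (see \code{\link{biomarker_panel}}).
#' @param crp_unit One of \code{"mg_dl"} (canonical) or \code{"mg_l"}
#'   (divided by 10).
#' @param glucose_unit One of \code{"mmol_l"} (canonical) or \code{"mg_dl"}
#'   (divided by 18.016, the molar mass scaling).
#' @param wbc_unit One of \code{"10e9_l"} or \code{"10e3_ul"}; the two are
#'   numerically identical, both are accepted for explicitness.
#' @return The panel in canonical units.
#' @export
convert_panel_units <- function(panel,
                                crp_unit = c("mg_dl", "mg_l"),
                                glucose_unit = c("mmol_l", "mg_dl"),
                                wbc_unit = c("10e9_l", "10e3_ul")) {
  crp_unit <- match.arg(crp_unit)
  glucose_unit <- match.arg(glucose_unit)
  wbc_unit <- match.arg(wbc_unit)
  if (crp_unit == "mg_l") panel$crp <- panel$crp / 10
  if (glucose_unit == "mg_dl") panel$glucose <- panel$glucose / 18.016
  # wbc: 10^3 cells/uL == 10^9 cells/L, no rescale needed
  panel
}

# extract the nine-biomarker panel from a cohort table that uses the CSV
# column dialect (albumin_g_l, ...), returning canonical short names
panel_from_cohort <- function(cohort) {
  cols <- panel_columns()
  missing <- setdiff(unname(cols), names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing panel columns: ", paste(missing, collapse = ", "))
  }
  out <- cohort[, unname(cols)]
  names(out) <- names(cols)
  out
}
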