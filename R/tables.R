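# Descriptive comparisons (survivors vs non-survivors), the
# comorbidity/acceleration odds-ratio table, and small reporting helpers.

#' Descriptive comparison of two outcome groups
#'
#' Categorical variables are compared with Pearson's chi-square test (no
#' continuity correction); continuous variables with the two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test, summarized as median (IQR) per
#' group. Variables constant in both groups carry no information for the
#' chi-square test and are flagged as skipped instead of producing an error.
#'
#' @param cohort Cohort data.frame.
#' @param group Name of the binary grouping column (default
#'   \code{"died_in_hospital"}).
#' @param categorical,continuous Character vectors of column names to
#'   compare.
#' @return data.frame with one row per variable: \code{variable, type,
#'   statistic, p, summary_g0, summary_g1, skipped}. Categorical summaries
#'   are "count (percent)" of the positive level; continuous summaries are
#'   "median (q1-q3)".
#' @export
table_one <- function(cohort, group = "died_in_hospital",
                      categorical = character(),
                      continuous = character()) {
  g <- cohort[[group]]
  if (is.null(g)) stop("grouping column not found: ", group)
  if (!all(g %in% c(0, 1))) stop("grouping must be binary 0/1")
  if (sum(g == 0) == 0 || sum(g == 1) == 0) {
    stop("both groups must be non-empty")
  }
  row_cat <- function(v) {
    x <- cohort[[v]]
    tab <- table(factor(x > 0, levels = c(FALSE, TRUE)), factor(g,
                 levels = c(0, 1)))
    smry <- sprintf("%d (%.1f%%)", tab[2, ], 100 * prop.table(tab, 2)[2, ])
    if (length(unique(x)) < 2) {
      return(data.frame(variable = v, type = "categorical",
                        statistic = NA_real_, p = NA_real_,
                        summary_g0 = smry[1], summary_g1 = smry[2],
                        skipped = TRUE))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(variable = v, type = "categorical",
               statistic = unname(ct$statistic), p = unname(ct$p.value),
               summary_g0 = smry[1], summary_g1 = smry[2], skipped = FALSE)
  }
  row_cont <- function(v) {
    x <- cohort[[v]]
    smry <- vapply(c(0, 1), function(gg) {
      q <- quantile(x[g == gg], c(0.5, 0.25, 0.75))
      sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
    }, character(1))
    wt <- suppressWarnings(wilcox.test(x[g == 1], x[g == 0]))
    data.frame(variable = v, type = "continuous",
               statistic = unname(wt$statistic), p = unname(wt$p.value),
               summary_g0 = smry[1], summary_g1 = smry[2], skipped = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(continuous, row_cont)),
    do.call(rbind, lapply(categorical, row_cat)))
  rownames(out) <- NULL
  out
}

#' Comorbidity odds ratios for the acceleration flag
#'
#' For each comorbidity, the 2x2 odds ratio of carrying the acceleration flag
#' given the comorbidity, with Woolf (logit) 95\% confidence interval and
#' Pearson chi-square p-value. With cell layout a = comorbid & accelerated,
#' b = comorbid & not, c = not comorbid & accelerated, d = neither, the odds
#' ratio is \eqn{ad/bc}. Any zero cell triggers the Haldane-Anscombe
#' correction (0.5 added to every cell), flagged in the output.
#'
#' @param cohort Cohort data.frame containing the comorbidity columns and the
#'   flag column.
#' @param comorbidities Character vector of comorbidity column names.
#' @param flag Name of the 0/1 acceleration column.
#' @param conf_level Confidence level.
#' @return data.frame with columns \code{comorbidity, a, b, c, d, or,
#'   ci_low, ci_high, p, corrected}.
#' @export
comorbidity_odds <- function(cohort, comorbidities = comorbidity_names(),
                             flag = "phenoage_accel", conf_level = 0.95) {
  f <- cohort[[flag]]
  if (is.null(f)) stop("flag column not found: ", flag)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(comorbidities, function(cm) {
    x <- cohort[[cm]]
    if (is.null(x)) stop("comorbidity column not found: ", cm)
    a <- sum(x == 1 & f == 1); b <- sum(x == 1 & f == 0)
    cc <- sum(x == 0 & f == 1); d <- sum(x == 0 & f == 0)
    corrected <- any(c(a, b, cc, d) == 0)
    aa <- a; bb <- b; cc2 <- cc; dd <- d
    if (corrected) {
      aa <- a + 0.5; bb <- b + 0.5; cc2 <- cc + 0.5; dd <- d + 0.5
    }
    or <- (aa * dd) / (bb * cc2)
    se <- sqrt(1 / aa + 1 / bb + 1 / cc2 + 1 / dd)
    tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
    p <- if (min(rowSums(tab)) == 0 || min(colSums(tab)) == 0) NA_real_ else
      unname(suppressWarnings(chisq.test(tab, correct = FALSE))$p.value)
    data.frame(comorbidity = cm, a = a, b = b, c = cc, d = d, or = or,
               ci_low = exp(log(or) - zq * se),
               ci_high = exp(log(or) + zq * se),
               p = p, corrected = corrected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentage of a count over a denominator, reporting convention
#'
#' The reporting layer's single rounding rule: percentages are printed to one
#' decimal place.
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return \code{round(100 * num / den, digits)}.
#' @examples
#' proportion_pct(291, 2950)  # hospital mortality, %
#' @export
proportion_pct <- function(num, den, digits = 1) {
  if (any(den <= 0)) stop("denominator must be positive")
  round(100 * num / den, digits)
}

#' Cohort-flow summary from raw counts
#'
#' Recomputes the derived percentages of a cohort-flow description (panel
#' availability among admissions, retained after readmission exclusion,
#' hospital mortality, acceleration prevalence overall and among
#' non-survivors) from their integer counts.
#'
#' @param admissions Total ICU admissions screened.
#' @param with_panel Admissions with the complete nine-test panel.
#' @param readmissions Readmissions excluded.
#' @param deaths Hospital deaths among analyzed patients.
#' @param accel Patients flagged as accelerated.
#' @param accel_deaths Accelerated patients among the deaths.
#' @return List of counts and the derived percentages (1 decimal).
#' @export
cohort_flow <- function(admissions, with_panel, readmissions, deaths,
                        accel, accel_deaths) {
  analyzed <- with_panel - readmissions
  list(admissions = admissions, with_panel = with_panel,
       analyzed = analyzed,
       panel_availability_pct = proportion_pct(with_panel, admissions),
       mortality_pct = proportion_pct(deaths, analyzed),
       accel_prevalence_pct = proportion_pct(accel, analyzed),
       accel_among_deaths_pct = proportion_pct(accel_deaths, deaths))
}
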