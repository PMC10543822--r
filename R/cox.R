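# Cox proportional-hazards fitting (Efron ties) and the sequential
# "one covariate per row" adjustment ladder. Model fitting is delegated to
# survival::coxph; this layer owns covariate screening, the ladder logic and
# a uniform result shape.

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling, Wald confidence
#' intervals, and Harrell's concordance on the fitted risk scores. Covariates
#' that are constant carry no partial-likelihood information; they are
#' reported with coefficient 0 (hazard ratio 1) and missing standard error
#' rather than failing the fit.
#'
#' @param time Follow-up time (event or censoring), days; positive.
#' @param event Binary event indicator (1 = died in hospital, 0 = censored at
#'   discharge).
#' @param covariates Numeric matrix or data.frame of covariates.
#' @param names Covariate names; defaults to the column names.
#' @param conf_level Confidence level for hazard-ratio intervals.
#' @param ties Tie-handling method, \code{"efron"} (default; day-resolution
#'   follow-up makes ties common) or \code{"breslow"}.
#' @return Object of class \code{cox_fit}: data.frame \code{coefficients}
#'   with columns \code{term, coef, se, hr, ci_low, ci_high, p}, plus
#'   \code{concordance}, \code{loglik}, \code{n}, \code{n_event} and the
#'   underlying \code{coxph} fit (\code{fit}, NULL when all covariates are
#'   constant).
#' @examples
#' cox_fit(c(1, 2, 3), c(1, 1, 1), matrix(c(1, 0, 1), ncol = 1,
#'         dimnames = list(NULL, "x")))
#' @export
cox_fit <- function(time, event, covariates, names = NULL,
                    conf_level = 0.95, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (!is.null(names)) colnames(covariates) <- names
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  if (length(time) != length(event) || nrow(covariates) != length(time)) {
    stop("time, event and covariates must have matching lengths")
  }
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be binary 0/1")
  if (sum(event) == 0) stop("no events: Cox model is not estimable")
  if (anyNA(covariates)) stop("covariates contain missing values")

  keep <- apply(covariates, 2, function(x) stats::sd(x) > 0)
  terms <- colnames(covariates)
  zq <- qnorm(1 - (1 - conf_level) / 2)

  out <- data.frame(term = terms, coef = 0, se = NA_real_, hr = 1,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  fit <- NULL
  cidx <- NA_real_
  ll <- NA_real_
  if (any(keep)) {
    x <- covariates[, keep, drop = FALSE]
    df <- data.frame(.time = time, .event = event, x, check.names = FALSE)
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = ties, model = TRUE,
                           x = TRUE)
    cf <- coef(fit)
    if (any(!is.finite(cf))) {
      stop("Cox model did not converge; coefficients: ",
           paste(sprintf("%s=%g", names(cf), cf), collapse = ", "))
    }
    se <- sqrt(diag(vcov(fit)))
    i <- match(colnames(x), out$term)
    out$coef[i] <- unname(cf)
    out$se[i] <- unname(se)
    out$hr[i] <- exp(unname(cf))
    out$ci_low[i] <- exp(unname(cf) - zq * unname(se))
    out$ci_high[i] <- exp(unname(cf) + zq * unname(se))
    out$p[i] <- 2 * pnorm(-abs(unname(cf) / unname(se)))
    cidx <- unname(survival::concordance(fit)$concordance)
    ll <- fit$loglik[length(fit$loglik)]
  }
  structure(list(coefficients = out, concordance = cidx, loglik = ll,
                 n = length(time), n_event = sum(event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards: %d patients, %d events\n",
              x$n, x$n_event))
  tab <- x$coefficients
  tab$hr <- round(tab$hr, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p <- signif(tab$p, 2)
  print(tab[, c("term", "hr", "ci_low", "ci_high", "p")], row.names = FALSE)
  if (is.finite(x$concordance)) {
    cat(sprintf("Harrell's C = %.3f\n", x$concordance))
  }
  invisible(x)
}

#' Sequential Cox adjustment ladder for a focal exposure
#'
#' Fits the nested model sequence \code{focal}, \code{focal + a1},
#' \code{focal + a1 + a2}, ... in the given adjuster order, reporting the
#' focal covariate's hazard ratio at each step, then fits the final full
#' model (all adjusters plus any \code{final_extra} covariates, e.g. a
#' dichotomized severity score) and reports every covariate's hazard ratio.
#' Covariates are forced in sequentially in the configured order by default;
#' setting \code{p_entry} switches to significance-gated forward entry, where
#' an adjuster is retained only if its Wald p-value on entry is below the
#' threshold.
#'
#' @param cohort Cohort data.frame.
#' @param focal Name of the exposure column whose adjusted hazard ratio is
#'   tracked (e.g. \code{"phenoage_accel"}).
#' @param ordered_adjusters Character vector of adjuster column names, in
#'   entry order.
#' @param final_extra Extra covariate names appended only to the final full
#'   model.
#' @param time,event Names of the follow-up and event columns.
#' @param p_entry Optional entry p-value threshold for significance-gated
#'   forward selection; \code{NULL} (default) forces every adjuster in.
#' @return Object of class \code{sequential_cox}: \code{ladder} (data.frame
#'   of the focal hazard ratio per step: \code{step, model, hr, ci_low,
#'   ci_high, p}), \code{final} (per-covariate rows of the full model),
#'   \code{final_fit} (the full-model \code{cox_fit}).
#' @export
sequential_cox <- function(cohort, focal, ordered_adjusters,
                           final_extra = character(),
                           time = "time_days", event = "died_in_hospital",
                           p_entry = NULL) {
  need <- c(focal, ordered_adjusters, final_extra, time, event)
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  }
  tt <- cohort[[time]]
  ev <- cohort[[event]]

  focal_row <- function(fit) {
    r <- fit$coefficients[fit$coefficients$term == focal, ]
    data.frame(hr = r$hr, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p)
  }

  included <- character()
  ladder <- NULL
  fit0 <- cox_fit(tt, ev, as.matrix(cohort[, focal, drop = FALSE]))
  ladder <- cbind(data.frame(step = 0L, model = focal,
                             stringsAsFactors = FALSE), focal_row(fit0))
  for (adj in ordered_adjusters) {
    trial <- c(focal, included, adj)
    fit_k <- cox_fit(tt, ev, as.matrix(cohort[, trial, drop = FALSE]))
    if (!is.null(p_entry)) {
      p_adj <- fit_k$coefficients$p[fit_k$coefficients$term == adj]
      if (!is.finite(p_adj) || p_adj >= p_entry) next
    }
    included <- c(included, adj)
    ladder <- rbind(ladder, cbind(
      data.frame(step = length(included),
                 model = paste(c(focal, included), collapse = " + "),
                 stringsAsFactors = FALSE),
      focal_row(fit_k)))
  }
  final_terms <- unique(c(focal, included, final_extra))
  final_fit <- cox_fit(tt, ev, as.matrix(cohort[, final_terms,
                                                drop = FALSE]))
  structure(list(ladder = ladder, final = final_fit$coefficients,
                 final_fit = final_fit),
            class = "sequential_cox")
}

#' @export
print.sequential_cox <- function(x, ...) {
  cat("Sequential Cox ladder (focal hazard ratio per adjustment step):\n")
  tab <- x$ladder
  tab$hr <- round(tab$hr, 3)
  tab$ci_low <- round(tab$ci_low, 3)
  tab$ci_high <- round(tab$ci_high, 3)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  cat("\nFinal full model:\n")
  print.cox_fit(x$final_fit)
  invisible(x)
}
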