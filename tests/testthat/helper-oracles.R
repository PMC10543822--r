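# Independent oracles, deliberately written as standalone arithmetic so they
# share no code path with the package implementation.

reference_panel <- function() {
  biomarker_panel(albumin = 40, creatinine = 80, glucose = 5.0, crp = 0.1,
                  lymphocyte_pct = 30, mcv = 90, rdw = 13, alp = 70, wbc = 7)
}

# direct one-line evaluation of the published transform, reading the constants
# file independently of phenoage_coefficients()
oracle_phenoage <- function(panel, age) {
  k <- jsonlite::read_json(
    system.file("extdata", "phenoage_levine_default.json",
                package = "phenoage"), simplifyVector = TRUE)
  xb <- k$intercept + k$albumin * panel$albumin +
    k$creatinine * panel$creatinine + k$glucose * panel$glucose +
    k$log_crp * log(panel$crp) + k$lymphocyte_pct * panel$lymphocyte_pct +
    k$mcv * panel$mcv + k$rdw * panel$rdw + k$alp * panel$alp +
    k$wbc * panel$wbc + k$age * age
  cumhaz <- exp(xb) * (exp(k$gompertz_gamma * k$horizon_months) - 1) /
    k$gompertz_gamma
  m <- 1 - exp(-cumhaz)
  # log(1 - m) = -cumhaz exactly, so the inversion is evaluated through the
  # cumulative hazard
  list(xb = xb, m = m,
       phenoage = k$inv_c + log((-k$inv_a) * cumhaz) / k$inv_b)
}

# algebraic inverse of the risk -> age mapping, for round-trip testing only
risk_from_phenoage <- function(pa, coeffs = phenoage_coefficients()) {
  1 - exp(exp(coeffs$inv_b * (pa - coeffs$inv_c)) / coeffs$inv_a)
}

# random physiologic panels for property tests
random_panels <- function(n) {
  biomarker_panel(albumin = runif(n, 20, 55),
                  creatinine = runif(n, 30, 600),
                  glucose = runif(n, 3, 20),
                  crp = runif(n, 0.01, 30),
                  lymphocyte_pct = runif(n, 2, 60),
                  mcv = runif(n, 70, 115),
                  rdw = runif(n, 11, 25),
                  alp = runif(n, 20, 500),
                  wbc = runif(n, 1, 40))
}

# exhaustive concordant-pair AUC (ties count one half)
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# grid maximization of the 3-observation Cox partial likelihood
# times (1,2,3) all events, x = (1,0,1): risk sets {1,2,3}, {2,3}, {3}
oracle_cox3_grid <- function() {
  logpl <- function(b) {
    u <- exp(b)
    log(u / (2 * u + 1)) + log(1 / (1 + u))
  }
  stats::optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
}
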