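---
title: "Phenotypic age and hospital mortality: models, simulator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic age and hospital mortality: models, simulator and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoage)
```

This vignette documents the scientific content of the package: the
phenotypic-age transform and its numerical treatment, the within-cohort
recalibration that defines age acceleration, what the synthetic ICU cohort
simulator does and does not emulate, the statistical battery, and the design
choices made where more than one defensible option existed.

## The phenotypic-age transform

Phenotypic age condenses chronological age and nine routine blood tests into
a single age-scaled risk summary. Three maps are composed:

1. **Linear predictor.** $xb = b_0 + \sum_i w_i x_i + w_{age}\,a$, where the
   $x_i$ are the biomarkers in canonical units (albumin g/L, creatinine
   µmol/L, glucose mmol/L, CRP mg/dL entering as $\ln x$, lymphocyte % of
   white cells, MCV fL, RDW %, ALP U/L, WBC $10^9$/L) and $a$ is
   chronological age in years.
2. **Gompertz mortality score.** Over a 120-month horizon with hazard
   growing at rate $\gamma$ per month,
   $M = 1 - \exp\{-e^{xb}(e^{120\gamma}-1)/\gamma\}$.
3. **Age-scale inversion.** $\text{PhenoAge} = c + \ln(a^\ast \ln(1-M))/b$
   with $a^\ast = -0.00553 < 0$, $b = 0.09165$, $c = 141.50225$, so that the
   inner product is positive for any $M \in (0,1)$.

The constants are not hard-coded: they load from a flat JSON file whose MD5
checksum is logged by the pipeline, so a different published coefficient set
can be dropped in verbatim and results remain auditable.

```{r}
phenoage_coefficients()
```

### Numerical treatment

- **CRP floor.** CRP below the assay detection limit is reported as 0;
  $\ln 0$ is undefined, so values below a configurable floor (default
  0.01 mg/dL) are raised to it.
- **Risk clamping.** `mortality_risk()` clamps into
  $[10^{-12}, 1-10^{-12}]$ so the inversion is always finite for arbitrary
  input.
- **Log-space composition.** Because $\ln(1-M)$ is exactly the negative
  Gompertz cumulative hazard, `compute_phenoage()` evaluates
  $\text{PhenoAge} = c + \{\ln(-a^\ast) + xb +
  \ln[(e^{120\gamma}-1)/\gamma]\}/b$ directly. This is algebraically
  identical to composing the three maps, but immune to the double-precision
  saturation of $M \to 1$, which would otherwise cap phenotypic age near
  121 years — a range severely ill ICU patients genuinely reach. The
  property test that exposed this (monotonicity of the score in every
  biomarker over random panels) is part of the suite.
- **Unit dialects.** Converters for CRP mg/L (÷10) and glucose mg/dL
  (÷18.016) are explicit arguments, never magnitude-based guesses.

## Recalibration and the acceleration flag

Three derived measures are computed per patient:

- the **signed age gap**, PhenoAge − age, in years. The signed convention
  (rather than a magnitude) is used because the direction of divergence is
  the quantity of interest — a magnitude is recoverable with `abs()`;
- the **residual** from the cohort-wide ordinary least squares regression of
  PhenoAge on chronological age. Residuals are indexed to the other patients
  in the same setting, a local recalibration that removes the tendency of
  the score to diverge upward with increasing age and absorbs
  setting-specific shifts in blood chemistry (acute inflammation,
  resuscitation fluids) common to all patients in that context;
- **PhenoAgeAccel**, the indicator of a *strictly positive* residual. A
  residual of exactly zero is not accelerated. Residuals within numerical
  noise of an exact fit (about $10^{-8}$ years at cohort scale, far below
  clinical resolution) are snapped to zero so a patient lying exactly on the
  cohort line is never flagged by floating-point accident.

Plain OLS is used, not a robust or weighted variant: the recalibration is a
simple regression by definition, and the fitted intercept is itself reported
as the cohort's recalibration constant — the excess of PhenoAge over
chronological age at which acceleration begins when the slope is near one.

## The synthetic cohort simulator

No patient-level data ship with the package; the simulator provides cohorts
whose hazard structure is known exactly, which turns every downstream stage
into a recovery experiment. Defaults emulate a mixed tertiary ICU cohort:
2950 patients, truncated-normal ages (mean 60, SD 16, bounds 18–95, giving
a median in the low 60s), comorbidity prevalences of a few percent
(chronic cardiovascular 7.7%, end-stage renal failure 4.3%, cirrhosis 2.2%,
diabetes 23.2%, elective surgery 27.4%), 10% expected hospital mortality,
and a survivors' stay that is log-normal with a 10-day median.

The generative core is a latent aging factor $z \sim N(\mu_i, 1)$, where
$\mu_i$ is a sum of comorbidity-specific increments (largest for end-stage
renal failure, then diabetes and cirrhosis), so accelerated aging is
enriched in comorbid patients. $z$ drives both

- the biomarker panel — each biomarker's mean shifts with $z$ in the
  direction of its scoring weight (e.g. CRP and RDW up, albumin and
  lymphocytes down), plus clinically motivated comorbidity shifts
  (creatinine +350 µmol/L in renal failure, glucose +3 mmol/L in diabetes,
  albumin −6 g/L in cirrhosis) and age trends, with lab-realistic
  dispersions truncated to physiologic ranges; and
- the death hazard — exponential with
  $\log \lambda_i = \beta_0 + \beta_z \mathbf{1}\{z_i > 0\} +
  \beta_A(\text{APACHE II}_i - 15)$, defaults $\beta_z = \ln 2$ (the latent
  factor doubles the hazard) and $\beta_A = 0.07$ per point. APACHE II is
  itself correlated with $z$ and age, making severity a genuine confounder.

Two points matter for interpretation. First, **acceleration enters survival
through the latent factor, not through the computed residual**: the measured
PhenoAgeAccel flag agrees with $\mathbf{1}\{z>0\}$ for only ~75% of patients
under the defaults, so it is a noisy measurement of truth. Attenuation of
its hazard ratio relative to the latent one is therefore an expected,
designed-in property — this is what makes recovery tests meaningful rather
than circular. Second, the **baseline hazard is tuned**, by root-finding on
$\beta_0$, so that the expected mortality
$\mathrm{mean}_i\,[1 - e^{-\lambda_i C_i}]$ (with $C_i$ the competing
discharge time) equals the target; `true_parameters()` re-derives the
expected mortality independently by quadrature over the discharge
distribution. Discharge acts as censoring for hospital death, matching the
usual Cox framing of in-hospital mortality. Follow-up is recorded in whole
days (ceiling), so ties are common, as in real hospital data — hence Efron
tie handling downstream.

Randomness follows one root seed that is expanded into fixed per-block
substream seeds (ages, flags, latent factor, biomarkers, severity,
discharge, death draws), so adding a later block can never perturb earlier
draws.

What the simulator does **not** emulate: admission-diagnosis mix, ICU
length-of-stay structure beyond the discharge distribution, longitudinal
biomarker trajectories, missingness, and real biomarker joint distributions
(no biomarker summary statistics were available to calibrate against;
distributions are built from standard reference intervals and are tunable).
Passing recovery tests therefore demonstrates correctness of the
*statistical machinery* under a plausible data-generating process, not
validity of the score in any particular hospital.

## The statistical battery

- **Discrimination.** Mann–Whitney AUC (ties half), DeLong placement-value
  variance and Wald intervals, and the paired DeLong test for correlated
  curves — computed with midranks, so no $O(n^2)$ pairwise pass. The
  implementation is cross-checked in the test suite against both exhaustive
  pair counting (all $n \le 30$) and the independent `pROC` implementation.
- **Cox models.** `survival::coxph` with Efron ties behind a uniform
  result surface; constant covariates are reported at hazard ratio 1 with
  missing standard error instead of failing (they carry no
  partial-likelihood information). Harrell's C comes from
  `survival::concordance`.
- **Sequential ladder.** The adjustment ladder adds one covariate per row
  in a fixed configured order (age, elective surgery, then the chronic
  conditions), reporting the focal hazard ratio at each step; the final full
  model appends the APACHE II > 15 indicator. Forced sequential entry is the
  default because a one-covariate-per-row table is what such ladders
  display regardless of significance; a significance-gated forward mode
  (`p_entry`) is available behind a flag. The severity score is
  dichotomized at >15 in the final model; the continuous score is available
  to callers.
- **Spline dose–response.** A 4-knot restricted cubic spline (Harrell
  truncated-power basis, normalized by the squared boundary span) of the
  residual, knots at the 5/35/65/95 percentiles — the standard placement
  for four knots — fitted in a Cox model; the curve is the log hazard ratio
  relative to residual 0 with delta-method bands, plus a 2-df Wald test of
  the nonlinear terms. The basis reproduces any linear function exactly
  (nonlinear coefficients vanish), is linear beyond the boundary knots, and
  recovers a plateau-shaped truth, all under test.
- **Descriptive tables.** Pearson chi-square without continuity correction
  for categorical variables, two-sided Mann–Whitney with median (IQR) for
  continuous ones; variables constant in both groups are flagged and
  skipped. All tests two-sided at $\alpha = 0.05$.
- **Comorbidity associations.** Per-condition 2×2 odds ratios for carrying
  the acceleration flag, Woolf logit intervals, Haldane–Anscombe 0.5
  correction on zero cells (flagged in the output).
- **Survival curves.** Kaplan–Meier by acceleration flag with the log-rank
  test; adjusted curves from the final Cox model by the mean-covariate
  method (all other covariates held at cohort means). Mean-covariate was
  chosen over stratified or inverse-weighted curves as the simplest method
  consistent with a single final proportional-hazards model.
- **ROC power.** Hanley–McNeil: with $Q_1 = \theta/(2-\theta)$,
  $Q_2 = 2\theta^2/(1+\theta)$,
  $V = [\theta(1-\theta) + (n_+{-}1)(Q_1-\theta^2) +
  (n_-{-}1)(Q_2-\theta^2)]/(n_+ n_-)$, the routine returns the smallest
  $n_+$ (with $n_- = \mathrm{round}(r\,n_+)$) such that
  $z_{1-\alpha/2}\sqrt{V_0} + z_{\text{power}}\sqrt{V_1} \le \theta -
  \theta_0$. The default negative:positive ratio of 10 corresponds to ~9%
  event prevalence.

```{r}
auroc_sample_size(0.60)
auroc_sample_size(0.65)
```

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: direct
one-line evaluation of the published transform (50 random panels, $10^{-9}$
years), closed-form normal equations for the recalibration (hand-computed
sums of squares), exhaustive pair counting for the AUC, a closed-form
three-observation partial-likelihood maximum ($\beta = -\tfrac12\ln 2$) for
the Cox fitter, hand evaluation of the truncated-power basis, and the
published 814/363 cohort sizes for the power routine.

Simulation-recovery checks run at sizes chosen to keep sampling error well
inside the asserted bands while remaining quick on a laptop: 200 cohorts of
3000 patients for hazard-ratio recovery (mean estimate within [1.9, 2.1] of
the true 2.0, interval coverage within [0.92, 0.98]); 100 seeds of 1500
patients for the spline type-I check (nonlinearity declared in at most 10%
of linear-truth datasets); 40 seeds of 3000 for plateau recovery (one-sided
sign test); and a single 50,000-patient cohort for mortality calibration
(within one absolute point of target). Single-draw checks at $n = 20000$
are averaged over three replicate seeds so they sit inside the sampling
variability of the estimator being checked.

## Known limitations

- The shipped coefficients are the widely used published set for the nine
  canonical-unit biomarkers; laboratories reporting in other units must use
  the explicit converters, and any recalibrated coefficient set must be
  supplied as a JSON file.
- Hospital discharge is treated as censoring, not as a competing risk; a
  Fine–Gray analysis is out of scope.
- Missing data are handled by complete-case analysis (the reader reports and
  can drop malformed rows under a permissive flag); there is no imputation
  machinery.
- The simulator's biomarker distributions are reference-interval based and
  tunable, not calibrated to any real cohort; absolute AUC values obtained
  on simulated data are not predictions for any hospital.
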