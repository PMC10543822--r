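# phenoage

Phenotypic-age scoring and hospital-mortality analysis for critically ill
cohorts.

Chronological age is a blunt marker of physiological reserve. The Levine
PhenoAge model estimates a *phenotypic* (biological) age from chronological
age plus nine routine blood tests — albumin, creatinine, glucose,
C-reactive protein, lymphocyte percentage, mean red-cell volume, red-cell
distribution width, alkaline phosphatase and white cell count. This package
implements the full analysis chain used to ask whether being biologically
older than one's chronological age predicts hospital mortality in intensive
care: scoring, within-cohort recalibration, and the statistical battery
(discrimination, sequential Cox adjustment, spline dose–response,
descriptive and association tables, ROC power calculation), together with a
synthetic ICU cohort simulator with known ground truth so every stage is
testable without patient data.

It is written for intensive-care researchers and biostatisticians who want
a reproducible, fully tested implementation of this pipeline.

## The model

The score is a weighted linear predictor over the nine biomarkers (CRP
enters as its natural log) and chronological age,

```
xb = b0 + Σ_i w_i · x_i + w_age · age ,
```

mapped through a Gompertz mortality score over a 120-month horizon,

```
M = 1 − exp( −e^xb · (e^{γ·120} − 1) / γ ) ,        γ = 0.0076927 /month,
```

and inverted back onto an age scale in years:

```
PhenoAge = 141.50225 + ln( −0.00553 · ln(1 − M) ) / 0.09165 .
```

All constants live in a versioned JSON file
(`inst/extdata/phenoage_levine_default.json`) and are injectable, because
the weights are unit-specific (albumin g/L, creatinine µmol/L, glucose
mmol/L, CRP mg/dL, WBC 10⁹/L) and silent unit mismatch is the dominant
failure mode. Explicit converters handle the common mg/L (CRP) and mg/dL
(glucose) lab dialects.

**Age acceleration** is defined relative to the cohort: PhenoAge is
regressed on chronological age by ordinary least squares over all patients,
and `PhenoAgeAccel` is the indicator of a strictly positive residual —
being biologically older than expected *compared to peers in the same
setting*. The regression intercept is the cohort's recalibration constant.

## Worked example

```r
library(phenoage)

panel <- biomarker_panel(albumin = 40, creatinine = 80, glucose = 5.0,
                         crp = 0.1, lymphocyte_pct = 30, mcv = 90,
                         rdw = 13, alp = 70, wbc = 7)
compute_phenoage(panel, age = 60)
#>          xb mortality_risk phenoage
#> 1 -8.040967     0.06152947 54.71313
```

A 60-year-old with this (healthy) panel has a linear predictor of −8.04, a
6.2% ten-year mortality score, and a phenotypic age of 54.7 years — about
five years *younger* than their chronological age.

The full pipeline on a simulated 2950-patient ICU cohort:

```r
report <- run_pipeline(config = simulation_config(n = 2950, seed = 1))
report
#> Biological-age mortality analysis report
#>   analyzed 2950 patients (0 readmissions excluded), 290 deaths (9.8%)
#>   recalibration: PhenoAge = 18.5 + 0.937 * age; accelerated 44.9%
#>   AUROC:
#>            measure   auc ci_low ci_high
#>  chronological_age 0.532  0.498   0.566
#>           phenoage 0.602  0.569   0.635
#>            age_gap 0.614  0.581   0.647
#>     accel_residual 0.616  0.583   0.649
#>     phenoage_accel 0.574  0.544   0.604
#>   DeLong phenoage vs chronological age: dAUC = 0.070, p = 5.55e-07
#>   focal HR: univariable 1.751 -> fully adjusted 1.375; final-model C = 0.645
#>   spline nonlinearity p = 0.00695; log-rank p = 2.06e-06
#>   power: n = 814 for AUC 0.60, n = 363 for AUC 0.65
```

Reading the report: phenotypic age and its recalibrated measures
discriminate hospital death clearly better than chronological age (AUC 0.60
vs 0.53, DeLong p < 10⁻⁶); the acceleration flag roughly doubles the death
hazard before adjustment and remains independently associated after
sequential adjustment for comorbidities and severity; and 814 patients
suffice to detect AUC 0.6 at 80% power with ~9% mortality. The simulator
embeds a latent aging factor that truly doubles the hazard, so these are
recoveries of known truth, not circular fits. `write_report(report, dir)`
emits JSON, plain-text tables and CSV curve grids.

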