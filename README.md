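# metsem

Sleep-mediated metabolic syndrome severity analysis by structural equation
modelling.

`metsem` is for epidemiologists and biostatisticians studying how habitual
sleep duration mediates the effects of age, socioeconomic status (SES),
physical activity, obesity, sleep latency, nap duration and night-shift
work on **continuous metabolic syndrome (MetS) severity** in adult cohorts.
It packages the whole workflow as tested, reusable components:

* **Cohort ingestion** with an auditable, ordered exclusion cascade whose
  per-rule counts are non-overlapping and sum exactly to
  `initial_n - final_n`, plus sex-stratified descriptive tables (pooled or
  Welch t-tests, Pearson chi-square).
* **Continuous MetS severity scoring** from the sex-specific weighted
  equations (natural-log triglycerides):

  ```
  men:   -5.5459 + 0.0135 WC - 0.0278 HDL + 0.0054 SBP + 0.8340 ln(TG) + 0.0105 Glu
  women: -7.7516 + 0.0162 WC - 0.0157 HDL + 0.0084 SBP + 0.8872 ln(TG) + 0.0206 Glu
  ```

  (WC cm, SBP mmHg, HDL/TG/glucose mg/dL; higher = worse metabolic profile.)
* **Derived variables**: a principal-component SES wealth index with
  tertile grouping, MET-hours activity categories (low 24–36.5 /
  moderate–45 / vigorous ≥ 45), and a skewness/kurtosis normality screen
  (|G1| ≤ 3, |G2| ≤ 10).
* **A maximum-likelihood SEM engine** (RAM parameterization
  `Σ = F(I-A)⁻¹S(I-A)⁻ᵀFᵀ`, analytic gradients, latent obesity measured by
  BMI/WC/BFM) with CFI/IFI/NFI/RMSEA fit indices, standardized solutions,
  per-equation R², and exact direct/indirect/total effect decomposition
  with case-resampling bootstrap confidence intervals.
* **A synthetic cohort generator** reproducing literature-anchored marginal
  moments and structural coefficient scale, so the entire pipeline is
  testable end-to-end without access to individual-level data.

Models are written in a compact text syntax:

```
obesity =~ bmi + wc + bfm
sleep_duration ~ age + ses + physical_activity + obesity + sleep_latency + nap_duration + night_shift
mets_severity ~ age + ses + physical_activity + obesity + sleep_latency + nap_duration + night_shift + sleep_duration
```

## Worked example

Fit the default sex-stratified mediation model to a synthetic male stratum
at the study's sample size:

```r
library(metsem)
tab <- generate_cohort(default_config("male"), seed = 42)
fit <- fit_ml(default_model(), tab)
fit
#> Structural equation model fit (ML, iterative)
#>   n = 2125, F_ML = 0.00940081, chi2 = 19.967, df = 16
#>   CFI = 0.999  IFI = 0.999  NFI = 0.997  RMSEA = 0.011  (acceptable)
#>   ...
decompose_effects(fit)
#> Standardized effects on mets_severity
#>          predictor direct indirect  total
#>                age  0.062   -0.005  0.057
#>                ses  0.026   -0.006  0.021
#>  physical_activity -0.057   -0.010 -0.067
#>            obesity  0.450   -0.001  0.449
#>      sleep_latency -0.007   -0.008 -0.016
#>       nap_duration  0.032   -0.007  0.026
#>        night_shift  0.010   -0.004  0.006
#>     sleep_duration  0.056    0.000  0.056
round(fit$r2, 3)
#>            bmi             wc            bfm sleep_duration  mets_severity
#>          0.805          0.861          0.749          0.139          0.214
```

Reading the output: the model fits the synthetic covariance structure well
(all incremental indices ≥ 0.99, RMSEA 0.011, against the conventional
CFI/IFI/NFI ≥ 0.90 and RMSEA ≤ 0.08 thresholds). Obesity dominates MetS
severity (standardized direct effect 0.450); each exposure's `indirect`
column is its effect routed through sleep duration (e.g. nap duration:
direct +0.032 but −0.007 through shortened sleep), and
`total = direct + indirect` holds exactly. The model explains 21.4% of the
variance in MetS severity in this stratum. Bootstrap confidence intervals
and p-values come from `bootstrap_effects()`; `run_pipeline()` runs the
whole flow (exclusions → derivation → scoring → screening → fits →
effects → combined two-sex report) from one seeded configuration and writes
a reproducible artifact bundle.

A thin command-line wrapper with `simulate` / `exclude` / `score` / `fit` /
`run` / `report` subcommands is installed at
`inst/scripts/mets-sem.R`.

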