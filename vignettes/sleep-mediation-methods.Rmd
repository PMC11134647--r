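---
title: "Modelling sleep-mediated effects on metabolic syndrome severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sleep-mediated effects on metabolic syndrome severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsem)
```

## The scientific problem

Metabolic syndrome (MetS) clusters central obesity, dyslipidaemia, raised
blood pressure and hyperglycaemia. Rather than the usual binary diagnosis,
`metsem` works with a *continuous severity score* — a sex-specific weighted
combination of waist circumference (WC), HDL cholesterol, systolic blood
pressure (SBP), log triglycerides (TG) and fasting glucose — which preserves
within-diagnosis variation and behaves like a z-score in adult populations.

The analytic question is *mediation*: several exposures (age, socioeconomic
status, physical activity, obesity, sleep latency, nap duration, night-shift
work) plausibly act on MetS severity both directly and through their effect
on habitual sleep duration. `metsem` formalises this as a sex-stratified
structural equation model (SEM) and decomposes each exposure's influence
into a direct path, an indirect path through sleep duration, and their sum.

## The severity score

For men and women respectively:

$$\mathrm{MetS}_m = -5.5459 + 0.0135\,\mathrm{WC} - 0.0278\,\mathrm{HDL}
  + 0.0054\,\mathrm{SBP} + 0.8340\,\ln \mathrm{TG} + 0.0105\,\mathrm{Glu}$$

$$\mathrm{MetS}_f = -7.7516 + 0.0162\,\mathrm{WC} - 0.0157\,\mathrm{HDL}
  + 0.0084\,\mathrm{SBP} + 0.8872\,\ln \mathrm{TG} + 0.0206\,\mathrm{Glu}$$

with WC in cm, SBP in mmHg, and HDL/TG/glucose in mg/dL. The logarithm is
natural. The coefficient magnitudes only make sense in these units, so unit
conversion is deliberately the caller's responsibility and is stated loudly
in the documentation rather than guessed from data. The score is strictly
increasing in WC, SBP, TG and glucose and strictly decreasing in HDL — a
property the test suite verifies over random inputs rather than assumes.

```{r}
mets_severity_score(100, 50, 120, 150, 100, "male")
mets_severity_score(100, 50, 120, 150, 100, "female")
```

A binary MetS flag is available through `classify_mets()`, but because no
single criteria set is universal the rule set is an explicit configuration
(`default_mets_criteria()` ships an NCEP-ATP-III-style default, labelled as
an assumption) and is never applied silently.

## Cohort ingestion and the exclusion cascade

`read_cohort()` reads a participant-level CSV (UTF-8, comma-separated,
header, `.` decimal, empty string = missing). Rows whose mandatory fields
fail to parse are *flagged* incomplete rather than dropped, so that the
exclusion cascade — not the parser — accounts for them.

`apply_exclusions()` applies an ordered rule list. Counting is sequential
by default: a record is attributed to the *first* rule that excludes it, so
per-rule counts are non-overlapping and sum exactly to
`initial_n - final_n`. This is the only counting convention under which a
published attrition flowchart's per-rule counts can add up exactly, which is
why it is the default; overlap-permitting counting is available with
`sequential = FALSE` and leaves the survivor set unchanged. The packaged
default cascade excludes, in order: cardiovascular disease, gestational
diabetes, thyroid disorder, cancer, depression, incomplete information,
inadequate energy intake (< 500 or ≥ 4200 kcal/day), alcohol use, current
smoking, and pregnancy.

Descriptive comparisons (`describe_by_sex()`) use the pooled-variance
Student t-test by default — the common default of the epidemiology software
family this pipeline mirrors — with Welch's test behind a flag, and Pearson
chi-square without continuity correction for categorical variables.
Percentages are computed at full precision and rounded only at formatting
time.

## Derived variables

**SES wealth index.** `ses_index()` standardizes the asset/education items
and extracts the first principal component of their *correlation* matrix.
Correlation (not covariance) PCA is standard for wealth indices because the
items are mixed-scale; a principal component's sign is arbitrary, so the
component is oriented to load positively on a designated wealth-positive
anchor item (education by default). Scores are cut into tertiles at the
empirical 1/3 and 2/3 quantiles (R's default quantile definition, type 7)
with lower-closed intervals, so ties at a cutpoint go upward deterministically.

**Physical activity.** `pa_category()` maps daily MET-hours to
low [24, 36.5], moderate (36.5, 45), vigorous ≥ 45. The conventional
reporting bands (36.6–44.9 for moderate) leave the tiny gaps
(36.5, 36.6) and (44.9, 45) unassigned; these are closed by continuity into
the moderate band so the function is total and monotone. Values below 24
MET-hours/day are physically impossible for a complete 24-hour diary
(resting expenditure alone is 24) and are labelled `below_range` with a
warning instead of silently binned.

**Normality screen.** `normality_screen()` computes the adjusted
Fisher–Pearson skewness (G1) and sample excess kurtosis (G2) — the
estimators of the mainstream commercial SEM software family — and flags a
variable acceptable when |skewness| ≤ 3 and |excess kurtosis| ≤ 10. A
failing variable warns but never aborts fitting: the screen is advisory,
matching how applied SEM workflows treat it.

## The structural equation engine

Models are written in a small plain-text language (`=~` measurement,
`~` regression, `~~` covariance, `#` comments) and compiled to the RAM
parameterization: an asymmetric matrix $A$ of loadings and paths, a
symmetric matrix $S$ of variances and covariances, and a filter $F$
selecting observed variables, with implied covariance

$$\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top .$$

Estimation minimises the normal-theory discrepancy
$F_{ML} = \ln|\Sigma| + \mathrm{tr}(S_n \Sigma^{-1}) - \ln|S_n| - p$
with the analytic gradient (four small matrix products per evaluation),
using a quasi-Newton optimizer. The default model encodes the conceptual
mediation diagram: a latent obesity factor measured by BMI, WC and body fat
mass (first indicator's loading fixed to 1 for identification, latent
variance free), every exogenous variable regressed into sleep duration and
into MetS severity, sleep duration into MetS severity, and all exogenous
variables freely covarying.

Numerical choices, all fixed and documented:

* start values: free loadings 0.5, paths 0, variances at the observed
  sample variances (latent variance at 0.05 × the reference indicator's
  variance); covariances between observed exogenous variables start at
  their sample values and pairs involving a latent at 0 — sample-covariance
  starts cost nothing and shorten the optimizer's path;
* convergence at gradient norm ≤ 1e−6 after the optimizer's own relative
  tolerance of 1e−12, iteration cap 1000, with one restart and a BFGS
  polish for the rare stalled fit; non-convergence is always flagged,
  never silent;
* variance parameters are bounded below at 1e−8 × the largest observed
  variance, so the search cannot leave the positive-definite region through
  a variance sign flip; non-positive-definite trial points return a large
  finite objective value so the line search backtracks;
* the sample covariance uses denominator $N-1$ and listwise deletion, the
  chi-square statistic is $(N-1)\,F_{ML}$, both the conventions of the
  software family this engine mirrors;
* standard errors come from the inverse information,
  $\widehat{\mathrm{Var}}(\hat\theta) = \tfrac{2}{N-1} H^{-1}$ with $H$ the
  numerically differentiated Hessian of $F_{ML}$ at the optimum.

For recursive models without latent variables, with a saturated exogenous
block and uncorrelated disturbances, the ML optimum coincides exactly with
per-equation least squares; `fit_ml()` recognises this case, solves it in
closed form from the sample covariance and verifies the gradient, which
makes case-resampling bootstraps of such models essentially free.
`engine = "iterative"` forces the quasi-Newton path (the test suite uses it
so the least-squares equivalence remains an genuine cross-check against
`stats::lm`).

The baseline independence model needed by the incremental fit indices has
the closed-form solution $\Sigma_b = \mathrm{diag}(S_n)$, giving
$\chi^2_b = -(N-1)\ln|R|$ with $R$ the sample correlation matrix. Indices
follow their standard definitions (NFI, IFI, CFI, and RMSEA with the
$\max(\chi^2 - df, 0)$ guard); a saturated model reports RMSEA 0 with an
explanatory note. Acceptability is flagged at CFI/IFI/NFI ≥ 0.90 and
RMSEA ≤ 0.08.

### Effects and inference

With the standardized path matrix $A^\*$, the total-effect matrix is
$(I - A^\*)^{-1} - I$; direct effects are entries of $A^\*$ and indirect
effects the difference, so `total = direct + indirect` holds *exactly*, not
approximately — the suite checks this to 1e−10 against brute-force path
enumeration on random recursive graphs. Since sleep duration has no
downstream mediator in the default model, its own indirect effect is
structurally zero.

The inference method for indirect effects is a nonparametric
case-resampling bootstrap (default B = 2000, percentile 95% intervals, seed
mandatory), with the two-sided p-value defined as the smallest level at
which the percentile interval excludes zero. Non-converged replicates are
dropped and counted; more than 20% triggers a warning, or an error in
strict mode. Categorical predictors (SES tertile, activity class) entering
a model are treated as numeric scores — common applied practice, and warned
about rather than hidden; the packaged pipeline instead carries the
*continuous* SES score and MET-hours into the model and keeps the
categorical versions for the descriptive table.

Sex stratification is two fully separate fits, never a multigroup model
with constraints, because the sexes differ in both measurement scale and
structural coefficients.

## The synthetic cohort generator

No individual-level data ship with the package, so `generate_cohort()` is a
first-class, tested module that emulates the statistical structure the
analysis assumes:

* exogenous variables jointly normal at literature-anchored sex-specific
  marginals (e.g. men's age 46.62 ± 8.01, sleep latency 27.71 ± 24.40 min,
  nap 66.48 ± 48.24 min) with a mild exchangeable correlation (0.1);
* MET-hours moments are not directly available; they are back-solved here
  from the printed activity-category frequencies by inverting the normal
  CDF at the 36.5/45 cutpoints, giving ≈ N(39.98, 10.92) for men and
  ≈ N(39.09, 4.19) for women;
* the minutes variables (latency, nap, night shift) are censored at zero
  after the normal draw. Structural outcomes are generated from the
  *censored* values, so the fitted regressions remain exactly correctly
  specified for the emitted columns — recovery studies then measure
  estimation error, not an artificial misspecification bias;
* latent obesity is standard normal, measured by BMI/WC/BFM at
  reliabilities 0.80/0.85/0.75 and literature-anchored indicator means/SDs;
* standardized structural paths into MetS severity are set to literature-reported
  sex-specific direct effects (sleep → MetS 0.050 in men, 0.010 in women).
  The paths *into* sleep duration are not printed anywhere usable —
  back-solving them from the reported indirect effects gives infeasible
  standardized magnitudes (e.g. −0.093/0.050 ≈ −1.9) — so the generator
  uses a documented plausible set (age −0.08, SES −0.12, activity −0.20,
  obesity −0.02, latency −0.18, nap −0.16, night shift −0.10), identical
  for both sexes;
* residual variances are solved so every structural variable has unit
  variance on the standardized scale, then affine maps produce the raw
  scales; with these defaults the model explains ≈ 0.21 of MetS severity
  variance in the male stratum, close to the reported 0.23;
* component-level mode also emits HDL, SBP, glucose and log-normal TG
  correlated with the severity outcome (correlations −0.40/0.45/0.50/0.55,
  a package calibration), so the scoring module has realistic inputs whose
  recomputed score tracks the structural severity column in rank order.

`true_effects()` returns the closed-form effect decomposition of the
generating model — the oracle for parameter-recovery tests.

What the generator deliberately does **not** emulate: the real cohort's
higher-order dependence (nonlinearities, interactions, heteroscedasticity),
item-level SES response patterns (unless `ses_items = TRUE`, which emits a
stylised 18-item battery), seasonal and measurement error structure, and any
joint behaviour beyond first and second moments plus the structural
skeleton. Passing recovery tests therefore demonstrates that the *engine*
estimates what it claims under the assumed data-generating process; it does
not validate the substantive conclusions on real data.

## Problem sizes used in validation

The packaged validation studies use sizes chosen to make Monte-Carlo error
small relative to the effects examined: 200 replicate cohorts of n = 4,000
for recovery of the sleep → MetS path (Monte-Carlo SE ≈ 0.001 on a true
value of 0.050), and 100–200 repetitions × B = 500 bootstrap replicates at
n = 2,000 for coverage of a zero indirect effect in the three-variable
mediation design, the design in which a null product path has a known
awkward sampling distribution. The percentile bootstrap's coverage there is
expected slightly above nominal; the accepted band is 93–97%.

## Known limitations

* Normal-theory ML only: no robust (Satorra–Bentler) corrections, no
  categorical-variable estimators (WLSMV), no missing-data ML (FIML) — the
  pipeline is listwise-complete by design, mirroring wholesale exclusion of
  incomplete records.
* No means/intercept structure: all models are covariance-structure models;
  effects are standardized and scale-free.
* Recursive models only; non-recursive (feedback) systems are rejected at
  parse time.
* The binary MetS flag is a labelled convenience, not a validated
  diagnosis.
* Bootstrap inference on the full latent model is computationally heavy
  (each replicate is a full quasi-Newton fit); for exploratory runs reduce
  `B` or disable the bootstrap in the pipeline configuration.

## A worked run

```{r, eval = FALSE}
out <- run_pipeline(list(
  input = list(simulate = TRUE),
  bootstrap = list(enabled = FALSE),
  seed = 17, out_dir = "run1"))
out$effects$male
```

The artifact bundle (`attrition.json`, `table1.csv`, `normality.json`,
`fit_male.json`, `fit_female.json`, `effects_male.csv`,
`effects_female.csv`, `table2.csv`, `MANIFEST.json`, `run.log`) is written
to `out_dir`; reruns with the same configuration and seed are
byte-identical.
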